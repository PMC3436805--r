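#' Build the weighted variant graph over one signature class
#'
#' Nodes are discordant pairs of a single signature class (and chromosome, or
#' chromosome pair for translocations), sorted by left-most position. An edge
#' joins two pairs when both their left and right ends are within the expected
#' insert size range (the larger `insert_max` of the two libraries). The edge
#' weight is the absolute difference of the predicted SV sizes; for
#' translocations, the sum of the absolute differences of the left-most
#' alignment positions of both mates. Built with a line sweep that stops the
#' inner scan at the first pair too far to the right.
#'
#' @param pairs an `sv_discordant` subset holding one signature class, sorted
#'   by `a_start`.
#' @return a `variant_graph`: node count, the node table, and an edge
#'   data.frame (`i`, `j`, `w` with node indices into the table).
#' @export
build_variant_graph <- function(pairs) {
  n <- nrow(pairs)
  g <- list(n = n, nodes = pairs,
            edges = data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  class(g) <- "variant_graph"
  if (n < 2L) return(g)
  if (is.unsorted(pairs$a_start)) stop("pairs must be sorted by left-most position")
  a <- pairs$a_start; be <- pairs$b_end; bs <- pairs$b_start
  imax <- pairs$insert_max
  tra <- startsWith(pairs$signature[1L], "TRA")
  size <- be - a
  max_range <- max(imax)
  upper <- findInterval(a + max_range, a)
  ei <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    if (upper[i] <= i) next
    j <- (i + 1L):upper[i]
    range_ij <- pmax(imax[i], imax[j])
    ok <- (a[j] - a[i]) <= range_ij & abs(be[j] - be[i]) <= range_ij
    j <- j[ok]
    if (!length(j)) next
    w <- if (tra) abs(a[j] - a[i]) + abs(bs[j] - bs[i]) else abs(size[j] - size[i])
    ei[[i]] <- data.frame(i = i, j = j, w = w)
  }
  ei <- ei[!vapply(ei, is.null, logical(1))]
  if (length(ei)) g$edges <- do.call(rbind, ei)
  g
}

#' Connected components of a variant graph
#'
#' @param graph a `variant_graph`.
#' @return list of integer vectors of node indices (singletons included;
#'   they are discarded at clique extraction).
#' @export
connected_components <- function(graph) {
  n <- graph$n
  if (n == 0L) return(list())
  if (!nrow(graph$edges)) return(as.list(seq_len(n)))
  ig <- igraph::make_graph(rbind(graph$edges$i, graph$edges$j),
                           n = n, directed = FALSE)
  memb <- igraph::components(ig)$membership
  unname(split(seq_len(n), memb))
}

#' Heuristic maximal clique within a connected component
#'
#' Seeds the clique with the component's minimum-weight edge and repeatedly
#' adds the node reachable through the smallest-weight edge incident to the
#' clique whose addition keeps it a clique; stops when no such node exists.
#' Ties in edge weight break toward smaller node index for determinism.
#' Singleton components yield no clique.
#'
#' @param component integer vector of node indices.
#' @param graph the `variant_graph` the component belongs to.
#' @return sorted integer vector of clique members, or NULL for singletons.
#' @export
extract_clique <- function(component, graph) {
  if (length(component) < 2L) return(NULL)
  e <- graph$edges
  e <- e[e$i %in% component & e$j %in% component, , drop = FALSE]
  if (!nrow(e)) return(NULL)
  e <- e[order(e$w, e$i, e$j), , drop = FALSE]
  adj <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(e))) {
    ik <- as.character(e$i[k]); jk <- as.character(e$j[k])
    assign(ik, c(get0(ik, adj, ifnotfound = integer(0)), e$j[k]), envir = adj)
    assign(jk, c(get0(jk, adj, ifnotfound = integer(0)), e$i[k]), envir = adj)
  }
  neighbors <- function(v) get0(as.character(v), adj, ifnotfound = integer(0))
  M <- c(e$i[1L], e$j[1L])
  repeat {
    added <- FALSE
    for (k in seq_len(nrow(e))) {
      u <- e$i[k]; v <- e$j[k]
      inu <- u %in% M; inv <- v %in% M
      if (inu == inv) next
      cand <- if (inu) v else u
      if (all(M %in% neighbors(cand))) {
        M <- c(M, cand)
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  sort(M)
}

## Innermost-coordinate breakpoint estimation per signature. For deletions the
## interval is [max upstream read end, min downstream read start); the other
## types mirror the rule on each side the reads approach from.
clique_interval <- function(members, signature) {
  a_end <- members$a_end; a_start <- members$a_start
  b_end <- members$b_end; b_start <- members$b_start
  switch(signature,
    DEL = c(max(a_end), min(b_start)),
    DUP = c(min(a_start), max(b_end)),
    INV_LEFT = c(max(a_end), max(b_end)),
    INV_RIGHT = c(min(a_start), min(b_start)),
    { ## translocations: one breakpoint per chromosome by pointing strand
      pa <- if (members$strand_a[1L] == "+") max(a_end) else min(a_start)
      pb <- if (members$strand_b[1L] == "+") max(b_end) else min(b_start)
      c(pa, pb)
    })
}

#' Turn a clique of discordant pairs into a paired-end SV call
#'
#' @param members the clique's rows of the `sv_discordant` table.
#' @param signature the shared signature class.
#' @return a one-row data.frame (imprecise PE call), or NULL when the
#'   coordinate estimate degenerates (start >= end).
#' @export
clique_to_call <- function(members, signature) {
  iv <- clique_interval(members, signature)
  tra <- startsWith(signature, "TRA")
  if (!tra && iv[1L] >= iv[2L]) return(NULL)
  data.frame(
    sv_type = if (tra) "TRA" else sub("_(LEFT|RIGHT)$", "", signature),
    side = if (startsWith(signature, "INV")) sub("^INV_", "", signature)
           else if (tra) signature else NA_character_,
    chrom = members$chrom_a[1L],
    start = iv[1L],
    end = if (tra) iv[1L] else iv[2L],
    chrom2 = if (tra) members$chrom_b[1L] else NA_character_,
    pos2 = if (tra) iv[2L] else NA_real_,
    pe_support = nrow(members),
    mapq_mean = mean(members$mapq),
    precise = FALSE,
    insert_max = max(members$insert_max),
    sd_insert = max(members$sd_insert),
    stringsAsFactors = FALSE)
}

#' Paired-end SV calling over all discordant pairs
#'
#' Orchestrates, per signature class and chromosome (pair), the variant graph
#' construction, connected components, one heuristic maximal clique per
#' component, and breakpoint estimation. Rearrangement types are analysed
#' separately, so calls of different types may overlap or nest.
#'
#' @param discordant an `sv_discordant` table from [extract_discordant()].
#' @param min_pairs minimum clique size reported (default 2; singletons are
#'   always discarded).
#' @return a `pe_calls` data.frame, one row per imprecise call, with member
#'   pair ids in the `members` list column.
#' @export
call_paired_end <- function(discordant, min_pairs = 2L) {
  empty <- data.frame(call_id = integer(0), sv_type = character(0), side = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      chrom2 = character(0), pos2 = numeric(0), pe_support = integer(0),
                      mapq_mean = numeric(0), precise = logical(0),
                      insert_max = numeric(0), sd_insert = numeric(0))
  empty$members <- list()
  class(empty) <- c("pe_calls", "data.frame")
  if (!nrow(discordant)) return(empty)
  key <- paste(discordant$signature, discordant$chrom_a, discordant$chrom_b)
  groups <- split(seq_len(nrow(discordant)), key)
  calls <- list()
  for (g in groups) {
    sub <- discordant[g, , drop = FALSE]
    sub <- sub[order(sub$a_start, sub$b_start), , drop = FALSE]
    graph <- build_variant_graph(sub)
    comps <- connected_components(graph)
    for (comp in comps) {
      M <- extract_clique(comp, graph)
      if (is.null(M) || length(M) < min_pairs) next
      call <- clique_to_call(sub[M, , drop = FALSE], sub$signature[1L])
      if (is.null(call)) next
      call$members <- list(sub$pair_id[M])
      calls[[length(calls) + 1L]] <- call
    }
  }
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$start, out$sv_type), , drop = FALSE]
  out$call_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pe_calls", "data.frame")
  out
}
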