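## Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

## Brute-force connected components by transitive closure of the adjacency
## matrix (oracle for the union-find/igraph path).
components_oracle <- function(n, edges) {
  adj <- diag(TRUE, n)
  for (k in seq_len(nrow(edges))) {
    adj[edges$i[k], edges$j[k]] <- TRUE
    adj[edges$j[k], edges$i[k]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  memb <- apply(adj, 1, function(row) min(which(row)))
  unname(split(seq_len(n), memb))
}

## Clique verification oracle.
is_clique <- function(nodes, edges) {
  if (length(nodes) < 2L) return(TRUE)
  key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
    if (a < b &&
        !(paste(min(nodes[a], nodes[b]), max(nodes[a], nodes[b])) %in% key))
      return(FALSE)
  }
  TRUE
}

## Is the clique unextendable: no node outside adjacent to every member?
is_maximal_clique <- function(nodes, n, edges) {
  outside <- setdiff(seq_len(n), nodes)
  for (u in outside) {
    if (is_clique(c(nodes, u), edges)) return(FALSE)
  }
  TRUE
}

## Exhaustive split-enumeration oracle for the double-DP split alignment:
## every split point (i, j) is scored with two independent glocal alignments
## (global in the consensus piece, local in the reference) via Biostrings.
split_oracle <- function(cons, ref, min_flank = 10L,
                         match = 5, mismatch = -4, gap_open = 10, gap_ext = 1) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                     mismatch = mismatch,
                                                     baseOnly = TRUE)
  glocal <- function(piece) {
    Biostrings::pairwiseAlignment(piece, ref, type = "global-local",
                                  substitutionMatrix = submat,
                                  gapOpening = gap_open, gapExtension = gap_ext,
                                  scoreOnly = TRUE)
  }
  n <- nchar(cons)
  max_gap <- max(0L, as.integer(floor(n / 2)) - 1L)
  best <- -Inf; bi <- NA; bj <- NA
  pre <- vapply(min_flank:(n - min_flank), function(i) glocal(substr(cons, 1, i)),
                numeric(1))
  suf_idx <- (min_flank + 1L):(n - min_flank + 1L)
  suf <- vapply(suf_idx, function(j) glocal(substr(cons, j, n)), numeric(1))
  for (i in min_flank:(n - min_flank)) {
    for (g in 0:max_gap) {
      j <- i + 1L + g
      if (j > n - min_flank + 1L) break
      sc <- pre[i - min_flank + 1L] + suf[j - min_flank - 1L + 1L]
      if (sc > best) { best <- sc; bi <- i; bj <- j }
    }
  }
  list(i = bi, j = bj, score = best)
}

## Non-template insertion that mismatches both junction landing sites
## (the reference bases after the prefix end and before the suffix start),
## so absorbing it into either flank alignment always scores worse than an
## unaligned microinsertion.
mismatch_ins <- function(ref, prefix_end, suffix_start, len) {
  after <- strsplit(substr(ref, prefix_end + 1, prefix_end + len), "")[[1]]
  before <- strsplit(substr(ref, suffix_start - len, suffix_start - 1), "")[[1]]
  vapply(seq_len(len), function(i) {
    allowed <- setdiff(c("A", "C", "G", "T"), c(after[i], before[i]))
    allowed[sample.int(length(allowed), 1)]
  }, character(1)) |> paste(collapse = "")
}

## Deterministic small simulation shared by several tests.
small_sim <- function(n_sv = c(DEL = 5), genome_length = 5e5, seed = 11, ...) {
  sv_simulate(genome_length = genome_length, n_sv = n_sv, coverage = 15,
              seed = seed, ...)
}

## A hand-built pair row in sv_pairs shape.
make_pair <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                      rl = 75L, mapq = 60L) {
  data.frame(pair_id = 1L, library_id = "lib1",
             chrom1 = chrom1, pos1 = pos1, end1 = pos1 + rl, strand1 = strand1,
             mapped1 = TRUE, mapq1 = mapq,
             chrom2 = chrom2, pos2 = pos2, end2 = pos2 + rl, strand2 = strand2,
             mapped2 = TRUE, mapq2 = mapq,
             clip1 = 0L, clip2 = 0L, seq1 = NA_character_, seq2 = NA_character_,
             stringsAsFactors = FALSE)
}

fr_profile <- function(median_insert = 300, sd_insert = 30, cutoff = 3)
  library_profile(median_insert, sd_insert, "FR", cutoff)
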