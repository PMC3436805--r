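#' Collect candidate split reads for paired-end SV calls
#'
#' Scans the pair tables once for single-anchored pairs (one mate mapped, one
#' unmapped). When the mapped mate lies within two insert-size standard
#' deviations of the nearest call breakpoint, the unmapped mate becomes a
#' split-read candidate for that call, oriented by the anchored mate and the
#' library default orientation so that all subsequent k-mer counting runs on a
#' single alignment direction. Optionally, soft-clipped mapped reads are
#' admitted as well. Each call's candidate set is truncated at `L`.
#'
#' @param pe_calls a `pe_calls` data.frame.
#' @param pairs_list one `sv_pairs` table per library (or a single table).
#' @param profiles matching list of [library_profile()]s.
#' @param L maximum candidates retained per call.
#' @param include_softclips also admit soft-clipped mapped reads near
#'   breakpoints.
#' @return data.frame of candidates: `call_id`, oriented sequence, anchor
#'   position and source read id.
#' @export
collect_split_candidates <- function(pe_calls, pairs_list, profiles, L = 1000L,
                                     include_softclips = FALSE) {
  empty <- data.frame(call_id = integer(0), seq = character(0),
                      anchor_pos = integer(0), read_id = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pe_calls)) return(empty)
  if (is.data.frame(pairs_list)) pairs_list <- list(pairs_list)
  if (inherits(profiles, "library_profile")) profiles <- list(profiles)

  ## sorted breakpoint table over all calls
  bp <- rbind(
    data.frame(chrom = pe_calls$chrom, pos = pe_calls$start, call_id = pe_calls$call_id),
    data.frame(chrom = ifelse(is.na(pe_calls$chrom2), pe_calls$chrom, pe_calls$chrom2),
               pos = ifelse(is.na(pe_calls$chrom2), pe_calls$end, pe_calls$pos2),
               call_id = pe_calls$call_id))
  bp <- bp[order(bp$chrom, bp$pos, bp$call_id), , drop = FALSE]
  bp_by_chrom <- split(bp, bp$chrom)

  ## Binary-search the closest breakpoint. The window is asymmetric: in the
  ## library-implied search direction the unmapped mate can sit up to about
  ## one insert away from the anchored read, while against the direction only
  ## `slop` (two insert-size SDs) of breakpoint-estimate error is tolerated.
  ## Ties between the flanking breakpoints go to the lower coordinate.
  nearest_call <- function(chrom, pos, fwd, slop, reach) {
    out <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      tab <- bp_by_chrom[[ch]]
      if (is.null(tab)) next
      sel <- which(chrom == ch)
      lo <- pmax(findInterval(pos[sel], tab$pos), 1L)
      hi <- pmin(lo + 1L, nrow(tab))
      d_lo <- abs(pos[sel] - tab$pos[lo])
      d_hi <- abs(tab$pos[hi] - pos[sel])
      lim_lo <- ifelse(fwd[sel], slop, reach)
      lim_hi <- ifelse(fwd[sel], reach, slop)
      ok_lo <- d_lo <= lim_lo
      ok_hi <- d_hi <= lim_hi
      use_lo <- ok_lo & (!ok_hi | d_lo <= d_hi)
      id <- ifelse(use_lo, tab$call_id[lo], ifelse(ok_hi, tab$call_id[hi], NA_integer_))
      out[sel] <- id
    }
    out
  }

  res <- list()
  rid <- 0L
  for (k in seq_along(pairs_list)) {
    p <- pairs_list[[k]]; prof <- profiles[[k]]
    slop <- 2 * prof$sd_insert
    reach <- prof$median_insert + slop
    single <- xor(p$mapped1, p$mapped2)
    if (any(single)) {
      sp <- p[single, , drop = FALSE]
      a1 <- sp$mapped1 # anchored mate is mate 1?
      a_chrom <- ifelse(a1, sp$chrom1, sp$chrom2)
      a_strand <- ifelse(a1, sp$strand1, sp$strand2)
      ## inner edge of the anchored read faces the breakpoint
      fwd <- if (prof$orientation == "RF") a_strand == "-" else a_strand == "+"
      a_pos <- ifelse(fwd, ifelse(a1, sp$end1, sp$end2), ifelse(a1, sp$pos1, sp$pos2))
      raw <- ifelse(a1, sp$seq2, sp$seq1)
      cid <- nearest_call(a_chrom, a_pos, fwd, slop, reach)
      keep <- !is.na(cid) & !is.na(raw)
      if (any(keep)) {
        sq <- raw[keep]
        need_rc <- fwd[keep] # anchored facing forward => mate sequenced reverse
        sq[need_rc] <- revcomp(sq[need_rc])
        res[[length(res) + 1L]] <- data.frame(
          call_id = cid[keep], seq = sq, anchor_pos = a_pos[keep],
          read_id = rid + seq_along(sq), stringsAsFactors = FALSE)
        rid <- rid + sum(keep)
      }
    }
    if (include_softclips) {
      for (mate in 1:2) {
        mp <- if (mate == 1L) p$mapped1 else p$mapped2
        cl <- if (mate == 1L) p$clip1 else p$clip2
        sel <- which(mp & cl > 0L & !is.na(if (mate == 1L) p$seq1 else p$seq2))
        if (!length(sel)) next
        sp <- p[sel, , drop = FALSE]
        ch <- if (mate == 1L) sp$chrom1 else sp$chrom2
        st <- if (mate == 1L) sp$strand1 else sp$strand2
        pos <- if (mate == 1L) sp$pos1 else sp$pos2
        en <- if (mate == 1L) sp$end1 else sp$end2
        raw <- if (mate == 1L) sp$seq1 else sp$seq2
        mid <- as.integer((pos + en) / 2)
        cid <- nearest_call(ch, mid, rep(TRUE, nrow(sp)), reach, reach)
        keep <- !is.na(cid)
        if (!any(keep)) next
        sq <- raw[keep]
        sq[st[keep] == "-"] <- revcomp(sq[st[keep] == "-"])
        res[[length(res) + 1L]] <- data.frame(
          call_id = cid[keep], seq = sq, anchor_pos = mid[keep],
          read_id = rid + seq_along(sq), stringsAsFactors = FALSE)
        rid <- rid + sum(keep)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  ## per-call cap
  out <- out[order(out$call_id, out$read_id), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$call_id),
                        function(ix) head(ix, L)), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the rearranged split-read alignment reference for a call
#'
#' Extracts reference windows around the two predicted breakpoints and
#' arranges them so the true junction appears as a standard "deletion-type"
#' prefix/suffix split: deletions need a plain extraction of the call
#' interval; tandem duplications swap the segment order; inversions
#' reverse-complement one segment; translocations concatenate the two
#' chromosome windows with order and strand fixed by the translocation class.
#'
#' @param genome named character vector of contig sequences.
#' @param call one-row `pe_calls` data.frame.
#' @param window flanking window per breakpoint side (bp); defaults to the
#'   call's library insert cutoff (median + 3 sd).
#' @return an `sv_reference`: concatenated sequence plus a segment map
#'   allowing back-translation of any position to genomic coordinates.
#' @export
build_sv_reference <- function(genome, call, window = NULL) {
  w <- as.integer(window %||% call$insert_max)
  clen <- function(ch) nchar(genome[[ch]])
  seg <- function(chrom, center_lo, center_hi, strand = "+") {
    gs <- max(0L, as.integer(center_lo) - w)
    ge <- min(clen(chrom), as.integer(center_hi) + w)
    list(chrom = chrom, g_start = gs, g_end = ge, strand = strand)
  }
  type <- call$sv_type
  segs <- if (type == "DEL") {
    list(seg(call$chrom, call$start, call$end)) # plain extraction of the interval
  } else if (type == "DUP") {
    list(seg(call$chrom, call$end, call$end), seg(call$chrom, call$start, call$start))
  } else if (type == "INV") {
    if (identical(call$side, "LEFT"))
      list(seg(call$chrom, call$start, call$start),
           seg(call$chrom, call$end, call$end, "-"))
    else
      list(seg(call$chrom, call$start, call$start, "-"),
           seg(call$chrom, call$end, call$end))
  } else { # TRA
    a <- call$chrom; b <- call$chrom2; pa <- call$start; pb <- call$pos2
    switch(call$side,
      TRA_1 = list(seg(a, pa, pa), seg(b, pb, pb)),
      TRA_2 = list(seg(a, pa, pa), seg(b, pb, pb, "-")),
      TRA_3 = list(seg(b, pb, pb), seg(a, pa, pa)),
      TRA_4 = list(seg(b, pb, pb, "-"), seg(a, pa, pa)))
  }
  pieces <- vapply(segs, function(s)
    genome_fetch(genome, s$chrom, s$g_start, s$g_end, s$strand), character(1))
  lens <- nchar(pieces)
  sv_end <- cumsum(lens)
  segmap <- data.frame(
    sv_start = sv_end - lens, sv_end = sv_end,
    chrom = vapply(segs, `[[`, character(1), "chrom"),
    g_start = vapply(segs, `[[`, numeric(1), "g_start"),
    g_end = vapply(segs, `[[`, numeric(1), "g_end"),
    strand = vapply(segs, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  structure(list(seq = paste(pieces, collapse = ""), segments = segmap,
                 sv_type = type, window = w), class = "sv_reference")
}

## Back-translate a junction coordinate in the rearranged reference.
## `side = "end"`: exclusive end of the prefix alignment; `side = "start"`:
## first position of the suffix alignment. Returns list(chrom, pos).
translate_breakpoint <- function(sv_ref, idx, side = c("end", "start")) {
  side <- match.arg(side)
  sm <- sv_ref$segments
  base <- if (side == "end") idx - 1L else idx # the adjacent aligned base
  k <- which(sm$sv_start <= base & base < sm$sv_end)[1L]
  if (is.na(k)) return(NULL)
  off <- idx - sm$sv_start[k]
  pos <- if (sm$strand[k] == "+") sm$g_start[k] + off else sm$g_end[k] - off
  list(chrom = sm$chrom[k], pos = as.integer(pos))
}

## k-mer position index of a reference sequence (0-based positions),
## skipping k-mers containing N.
kmer_index <- function(seq, k = 7L) {
  L <- nchar(seq)
  if (L < k) return(list())
  kmers <- substring(seq, seq_len(L - k + 1L), k:L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  split(which(ok) - 1L, kmers[ok])
}

#' Count k-mer hits of a read by alignment diagonal
#'
#' Maps each read k-mer (skipping those containing N) against the SV
#' reference index and tallies hits per alignment diagonal (reference offset
#' minus read offset). Diagonals are post-processed in decreasing hit order
#' and each read k-mer is flagged as used once one of its diagonals has been
#' processed, so every k-mer counts toward a single, best-supported diagonal.
#'
#' @param read_seq candidate read sequence (already oriented to the single
#'   allowed alignment direction).
#' @param index k-mer index from `kmer_index()` over the SV reference.
#' @param k k-mer length (default 7).
#' @return a `diagonal_profile`: diagonal indices, final hit counts, the mean
#'   read offset of the counted k-mers per diagonal, and the number of read
#'   k-mers; or NULL when the read is shorter than `k`.
#' @export
diagonal_hits <- function(read_seq, index, k = 7L) {
  L <- nchar(read_seq)
  if (L < k) return(NULL)
  kmers <- substring(read_seq, seq_len(L - k + 1L), k:L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  n_kmers <- sum(valid)
  hits_list <- index[kmers]
  hit_len <- lengths(hits_list)
  hit_len[!valid] <- 0L
  kid <- rep(seq_along(kmers), hit_len)
  refpos <- unlist(hits_list[hit_len > 0L], use.names = FALSE)
  if (is.null(refpos) || !length(refpos)) {
    return(structure(list(diag = integer(0), count = integer(0),
                          mean_offset = numeric(0), n_kmers = n_kmers),
                     class = "diagonal_profile"))
  }
  diag <- refpos - (kid - 1L)
  tab <- table(diag)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  dvals <- as.integer(names(tab))[ord]
  used <- logical(length(kmers))
  out_d <- integer(0); out_c <- integer(0); out_m <- numeric(0)
  for (d in dvals) {
    sel <- which(diag == d)
    sel <- sel[!used[kid[sel]]]
    if (length(sel)) {
      out_d <- c(out_d, d)
      out_c <- c(out_c, length(sel))
      out_m <- c(out_m, mean(kid[sel] - 1L))
      used[kid[sel]] <- TRUE
    }
  }
  ord2 <- order(out_d)
  structure(list(diag = out_d[ord2], count = out_c[ord2],
                 mean_offset = out_m[ord2], n_kmers = n_kmers),
            class = "diagonal_profile")
}

#' Select a read's SV offset from its diagonal profile
#'
#' Discards diagonals with fewer than `k_min` hits; requires at least two
#' survivors whose two best diagonals jointly cover at least half the read's
#' k-mers; sorts survivors by diagonal index and reports the offset between
#' the most supported pair of consecutive diagonals. For a true SV junction
#' this offset equals the apparent deletion length in the rearranged
#' reference.
#'
#' @param profile a `diagonal_profile` from [diagonal_hits()].
#' @param k_min minimum hits per retained diagonal (default 3).
#' @return list with `offset`, the diagonal pair, and `prefix_diag` (the pair
#'   member whose k-mers sit earlier in the read, used to anchor the read in
#'   the consensus frame); or NULL when any filter rejects the read.
#' @export
select_read_offset <- function(profile, k_min = 3L) {
  if (is.null(profile)) return(NULL)
  keep <- profile$count >= k_min
  if (sum(keep) < 2L) return(NULL)
  d <- profile$diag[keep]; cnt <- profile$count[keep]; mo <- profile$mean_offset[keep]
  top2 <- sum(sort(cnt, decreasing = TRUE)[1:2])
  if (top2 < profile$n_kmers / 2) return(NULL)
  ## most supported consecutive pair in diagonal order
  if (length(d) == 2L) {
    pick <- 1L
  } else {
    pair_support <- cnt[-length(cnt)] + cnt[-1L]
    pick <- which.max(pair_support)
  }
  d1 <- d[pick]; d2 <- d[pick + 1L]
  prefix_diag <- if (mo[pick] <= mo[pick + 1L]) d1 else d2
  list(offset = d2 - d1, diags = c(d1, d2), prefix_diag = prefix_diag)
}

#' Vote on the SV offset across a call's candidate reads
#'
#' The modal per-read offset wins; the call fails split-read refinement when
#' fewer than `min_split` reads support the winner. Ties break toward the
#' offset closest to the paired-end predicted SV size, then toward the
#' smaller offset.
#'
#' @param offsets integer vector of per-read offsets.
#' @param min_split minimum supporting split reads (default 2).
#' @param pe_size paired-end predicted SV size (NA for translocations).
#' @return list with the winning `offset` and `support` (indices of the
#'   supporting reads), or NULL.
#' @export
vote_offset <- function(offsets, min_split = 2L, pe_size = NA_real_) {
  if (!length(offsets)) return(NULL)
  tab <- table(offsets)
  mx <- max(tab)
  winners <- as.integer(names(tab)[tab == mx])
  if (length(winners) > 1L) {
    if (!is.na(pe_size)) {
      dd <- abs(winners - pe_size)
      winners <- winners[dd == min(dd)]
    }
    winners <- min(winners)
  }
  support <- which(offsets == winners)
  if (length(support) < min_split) return(NULL)
  list(offset = winners, support = support)
}

#' Gapless majority-vote consensus of the supporting split reads
#'
#' Reads are placed in the rearranged-reference coordinate frame by their
#' prefix diagonal; each consensus column takes the modal nucleotide over the
#' covering reads (ties break toward the earliest read). Uncovered edge
#' columns are trimmed; internal coverage gaps fail the call.
#'
#' @param seqs supporting read sequences (oriented).
#' @param placements per-read start position in the reference frame (the
#'   prefix diagonal).
#' @return list with the consensus string and its frame `start`, or NULL for
#'   non-overlapping placements.
#' @export
consensus_sequence <- function(seqs, placements) {
  if (!length(seqs)) return(NULL)
  lens <- nchar(seqs)
  lo <- min(placements); hi <- max(placements + lens)
  width <- hi - lo
  mat <- matrix(NA_character_, nrow = length(seqs), ncol = width)
  for (r in seq_along(seqs)) {
    s <- placements[r] - lo
    mat[r, (s + 1):(s + lens[r])] <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
  }
  cov <- colSums(!is.na(mat))
  if (any(cov == 0L)) {
    covered <- which(cov > 0L)
    if (any(diff(covered) > 1L)) return(NULL) # non-overlapping placements
  }
  cols <- which(cov > 0L)
  cons <- vapply(cols, function(j) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    tb <- table(col)
    cands <- names(tb)[tb == max(tb)]
    if (length(cands) == 1L) return(cands)
    ## tie: take the base of the earliest covering read among the tied bases
    col2 <- mat[, j]
    for (r in seq_along(col2)) if (!is.na(col2[r]) && col2[r] %in% cands) return(col2[r])
    cands[1L]
  }, character(1))
  list(seq = paste(cons, collapse = ""), start = lo + cols[1L] - 1L)
}

#' Breakpoint-resolving split alignment of a consensus sequence
#'
#' Double dynamic programming: a forward scoring vector `f` (best affine-gap
#' alignment of every consensus prefix, global in the prefix and free at the
#' reference ends) and a reverse vector `r` (same for every suffix) are
#' combined to maximise `f_i + r_j` over split points `j >= i + 1`. `j > i+1`
#' yields a non-template microinsertion `c[i+1..j-1]`; ties at `j = i + 1`
#' define a microhomology tract, with the breakpoint left-aligned.
#'
#' @param cons consensus sequence.
#' @param sv_ref an `sv_reference` (or a plain reference string).
#' @param scores list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param min_flank minimum aligned consensus length on each junction side.
#' @return list: split indices `i`, `j` (1-based consensus positions), total
#'   `score`, `quality` (matches over aligned consensus length),
#'   0-based reference indices `ref_prefix_end` (exclusive) and
#'   `ref_suffix_start`, the microinsertion string, and `homlen`; or NULL
#'   when no valid split exists.
#' @export
split_alignment <- function(cons, sv_ref,
                            scores = list(match = 5, mismatch = -4,
                                          gap_open = -10, gap_ext = -1),
                            min_flank = 10L) {
  ref <- if (inherits(sv_ref, "sv_reference")) sv_ref$seq else sv_ref
  n <- nchar(cons); L <- nchar(ref)
  if (n < 2L * min_flank + 1L || L < 1L) return(NULL)
  fwd <- .gotoh_prefix(cons, ref, scores$match, scores$mismatch,
                       scores$gap_open, scores$gap_ext)
  rev_c <- paste(rev(strsplit(cons, "", fixed = TRUE)[[1]]), collapse = "")
  rev_r <- paste(rev(strsplit(ref, "", fixed = TRUE)[[1]]), collapse = "")
  bwd <- .gotoh_prefix(rev_c, rev_r, scores$match, scores$mismatch,
                       scores$gap_open, scores$gap_ext)
  f <- fwd$best
  r <- rev(bwd$best) # r[j] = best suffix alignment of c[j..n]
  r_pos <- rev(bwd$pos); r_nm <- rev(bwd$nmatch)

  max_gap <- max(0L, as.integer(floor(n / 2)) - 1L)
  best <- -Inf; bi <- NA_integer_; bg <- NA_integer_
  i_range <- min_flank:(n - min_flank)
  for (g in 0:max_gap) {
    i_ok <- i_range[i_range + 1L + g <= n - min_flank + 1L]
    if (!length(i_ok)) break
    tot <- f[i_ok] + r[i_ok + 1L + g]
    m <- max(tot)
    if (m > best) { best <- m; bg <- g; bi <- i_ok[which.max(tot)] }
  }
  if (!is.finite(best)) return(NULL)
  homlen <- 0L
  if (bg == 0L) {
    i_ok <- i_range[i_range + 1L <= n - min_flank + 1L]
    tie <- i_ok[f[i_ok] + r[i_ok + 1L] >= best - 1e-9]
    ## consecutive optimal run containing the argmax = microhomology tract
    runs <- split(tie, cumsum(c(1L, diff(tie) != 1L)))
    run <- runs[[which(vapply(runs, function(x) bi %in% x, logical(1)))[1L]]]
    bi <- min(run) # left-align the breakpoint
    homlen <- length(run) - 1L
  }
  bj <- bi + 1L + bg
  micro <- if (bg > 0L) substr(cons, bi + 1L, bj - 1L) else ""
  matches <- fwd$nmatch[bi] + r_nm[bj]
  aligned <- bi + (n - bj + 1L)
  list(i = bi, j = bj, score = best,
       quality = matches / aligned,
       ref_prefix_end = fwd$pos[bi],            # 0-based exclusive end
       ref_suffix_start = L - r_pos[bj],        # 0-based start
       microinsertion = micro, homlen = homlen,
       matches = matches, aligned = aligned)
}

## Genomic breakpoints + SV length from a split result, per call type.
resolve_breakpoints <- function(sv_ref, split, call) {
  left <- translate_breakpoint(sv_ref, split$ref_prefix_end, "end")
  right <- translate_breakpoint(sv_ref, split$ref_suffix_start, "start")
  if (is.null(left) || is.null(right)) return(NULL)
  type <- sv_ref$sv_type
  if (type == "DEL") {
    if (right$pos <= left$pos) return(NULL)
    list(start = left$pos, end = right$pos, sv_length = right$pos - left$pos)
  } else if (type == "DUP") {
    if (left$pos <= right$pos) return(NULL)
    list(start = right$pos, end = left$pos, sv_length = left$pos - right$pos)
  } else if (type == "INV") {
    s <- min(left$pos, right$pos); e <- max(left$pos, right$pos)
    if (e <= s) return(NULL)
    list(start = s, end = e, sv_length = e - s)
  } else { # TRA: assign by chromosome of each junction side
    if (left$chrom == call$chrom && right$chrom != call$chrom)
      list(start = left$pos, pos2 = right$pos, sv_length = NA_real_)
    else if (right$chrom == call$chrom && left$chrom != call$chrom)
      list(start = right$pos, pos2 = left$pos, sv_length = NA_real_)
    else NULL
  }
}

#' Refine one paired-end call with split reads
#'
#' Runs the full split-read pipeline for a call: SV reference construction,
#' k-mer diagonal counting per candidate, per-read offset selection, offset
#' voting, gapless consensus, split alignment and back-translation. On
#' success the call becomes precise with single-nucleotide breakpoints; any
#' stage failure returns the paired-end call unchanged. The split-read
#' predicted length must confirm the paired-end length within
#' `length_tol` (default 10%).
#'
#' @param call one-row `pe_calls` data.frame.
#' @param cand the call's candidate table from [collect_split_candidates()].
#' @param genome named character vector of contigs.
#' @param k,k_min k-mer length and minimum diagonal hits.
#' @param min_split minimum supporting split reads.
#' @param min_quality minimum consensus alignment quality (identity fraction).
#' @param length_tol allowed relative difference between split-read and
#'   paired-end SV length.
#' @param scores affine alignment scores, see [split_alignment()].
#' @return the (possibly refined) one-row call data.frame.
#' @export
refine_call <- function(call, cand, genome, k = 7L, k_min = 3L, min_split = 2L,
                        min_quality = 0.8, length_tol = 0.1,
                        scores = list(match = 5, mismatch = -4,
                                      gap_open = -10, gap_ext = -1)) {
  fallback <- function() {
    call$sr_support <- 0L; call$consensus <- NA_character_
    call$srq <- NA_real_; call$inslen <- NA_integer_
    call$ins_seq <- NA_character_; call$homlen <- NA_integer_
    call$sv_length <- if (call$sv_type == "TRA") NA_real_ else call$end - call$start
    call
  }
  if (is.null(cand) || !nrow(cand)) return(fallback())
  sv_ref <- build_sv_reference(genome, call)
  index <- kmer_index(sv_ref$seq, k)
  sel <- lapply(cand$seq, function(s)
    select_read_offset(diagonal_hits(s, index, k), k_min))
  ok <- !vapply(sel, is.null, logical(1))
  if (sum(ok) < min_split) return(fallback())
  offsets <- vapply(sel[ok], `[[`, numeric(1), "offset")
  pe_size <- if (call$sv_type == "TRA") NA_real_ else call$end - call$start
  vote <- vote_offset(offsets, min_split, pe_size)
  if (is.null(vote)) return(fallback())
  idx_ok <- which(ok)[vote$support]
  placements <- vapply(sel[idx_ok], `[[`, numeric(1), "prefix_diag")
  cons <- consensus_sequence(cand$seq[idx_ok], placements)
  if (is.null(cons)) return(fallback())
  split <- split_alignment(cons$seq, sv_ref, scores)
  if (is.null(split) || split$quality < min_quality) return(fallback())
  if (nchar(split$microinsertion) >= nchar(cons$seq) / 2) return(fallback())
  bp <- resolve_breakpoints(sv_ref, split, call)
  if (is.null(bp)) return(fallback())
  if (!is.na(bp$sv_length)) {
    if (abs(bp$sv_length - pe_size) > length_tol * pe_size) return(fallback())
    call$start <- bp$start; call$end <- bp$end
  } else {
    call$start <- bp$start; call$end <- bp$start; call$pos2 <- bp$pos2
  }
  call$precise <- TRUE
  call$sr_support <- length(vote$support)
  call$consensus <- cons$seq
  call$srq <- split$quality
  call$inslen <- nchar(split$microinsertion)
  call$ins_seq <- if (nzchar(split$microinsertion)) split$microinsertion else NA_character_
  call$homlen <- split$homlen
  call$sv_length <- if (is.na(bp$sv_length)) NA_real_ else bp$sv_length
  call
}

#' Refine all paired-end calls with split reads
#'
#' @param pe_calls a `pe_calls` data.frame.
#' @param candidates candidate table from [collect_split_candidates()].
#' @param genome named character vector of contigs.
#' @param ... passed to [refine_call()].
#' @return the call table with refined (precise) coordinates where split-read
#'   support confirmed the call.
#' @export
refine_calls <- function(pe_calls, candidates, genome, ...) {
  if (!nrow(pe_calls)) {
    pe_calls$sr_support <- integer(0); pe_calls$consensus <- character(0)
    pe_calls$srq <- numeric(0); pe_calls$inslen <- integer(0)
    pe_calls$ins_seq <- character(0); pe_calls$homlen <- integer(0)
    pe_calls$sv_length <- numeric(0)
    return(pe_calls)
  }
  by_call <- split(candidates, candidates$call_id)
  rows <- lapply(seq_len(nrow(pe_calls)), function(r) {
    call <- pe_calls[r, , drop = FALSE]
    refine_call(call, by_call[[as.character(call$call_id)]], genome, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- class(pe_calls)
  out
}
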