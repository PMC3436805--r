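na0 <- function(x) ifelse(is.na(x), 0, x)

## intersection / max(length): the reciprocal-overlap criterion
reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmin(e1, e2) - pmax(s1, s2)
  pmax(inter, 0) / pmax(e1 - s1, e2 - s2)
}

#' Merge complementary left- and right-spanning inversion calls
#'
#' Pairs left- with right-spanning inversion calls whose intervals have a
#' reciprocal overlap of at least `min_overlap`, merging best-first (smallest
#' absolute breakpoint distance first); each call merges at most once and
#' unmerged calls pass through. Merged coordinates come from the precise
#' partner when exactly one partner is precise; from the higher split-read
#' support when both are; otherwise from the midpoint of the two imprecise
#' intervals. Merging never moves a precise call's breakpoints.
#'
#' @param calls call table (any types; only INV rows are touched).
#' @param min_overlap reciprocal overlap threshold (default 0.8).
#' @return the call table with merged inversion rows.
#' @export
merge_inversions <- function(calls, min_overlap = 0.8) {
  inv <- which(calls$sv_type == "INV")
  if (length(inv) < 2L) return(calls)
  li <- inv[calls$side[inv] == "LEFT"]
  ri <- inv[calls$side[inv] == "RIGHT"]
  if (!length(li) || !length(ri)) return(calls)
  cand <- expand.grid(l = li, r = ri)
  cand <- cand[calls$chrom[cand$l] == calls$chrom[cand$r], , drop = FALSE]
  if (!nrow(cand)) return(calls)
  cand$ro <- reciprocal_overlap(calls$start[cand$l], calls$end[cand$l],
                                calls$start[cand$r], calls$end[cand$r])
  cand <- cand[cand$ro >= min_overlap, , drop = FALSE]
  if (!nrow(cand)) return(calls)
  cand$dist <- abs(calls$start[cand$l] - calls$start[cand$r]) +
    abs(calls$end[cand$l] - calls$end[cand$r])
  cand <- cand[order(cand$dist, cand$l, cand$r), , drop = FALSE]
  used <- logical(nrow(calls))
  drop <- integer(0)
  for (k in seq_len(nrow(cand))) {
    l <- cand$l[k]; r <- cand$r[k]
    if (used[l] || used[r]) next
    used[l] <- TRUE; used[r] <- TRUE
    pl <- calls$precise[l]; pr <- calls$precise[r]
    base <- if (pl && !pr) l
      else if (pr && !pl) r
      else if (pl && pr) { if (na0(calls$sr_support[r]) > na0(calls$sr_support[l])) r else l }
      else l
    other <- if (base == l) r else l
    sup_l <- calls$pe_support[l]; sup_r <- calls$pe_support[r]
    if (!pl && !pr) { # midpoint of the two imprecise intervals
      calls$start[base] <- round((calls$start[l] + calls$start[r]) / 2)
      calls$end[base] <- round((calls$end[l] + calls$end[r]) / 2)
    }
    calls$pe_support[base] <- sup_l + sup_r
    calls$mapq_mean[base] <- mean(c(calls$mapq_mean[base], calls$mapq_mean[other]))
    calls$sr_support[base] <- na0(calls$sr_support[l]) + na0(calls$sr_support[r])
    calls$support_left[base] <- sup_l
    calls$support_right[base] <- sup_r
    calls$side[base] <- "BOTH"
    calls$merged_from[[base]] <- c(calls$call_id[l], calls$call_id[r])
    drop <- c(drop, other)
  }
  if (length(drop)) calls <- calls[-drop, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Merge complementary translocation junction calls
#'
#' Pairs translocation calls that support the same relative orientation
#' (non-inverted classes with non-inverted, inverted with inverted), share
#' both chromosomes, and whose predicted breakpoints on the insertion
#' chromosome are less than `z` bp apart; pairs with minimal insertion-site
#' distance merge first.
#'
#' @param calls call table (only TRA rows are touched).
#' @param z maximum insertion-position distance in bp (default 300, strict).
#' @return the call table with merged translocation rows (the partner
#'   junction's segment-side coordinate is kept in `pos2_b`).
#' @export
merge_translocations <- function(calls, z = 300) {
  tra <- which(calls$sv_type == "TRA")
  if (length(tra) < 2L) return(calls)
  noninv <- c("TRA_1", "TRA_3"); invc <- c("TRA_2", "TRA_4")
  cand <- expand.grid(a = tra, b = tra)
  cand <- cand[cand$a < cand$b, , drop = FALSE]
  ok <- (calls$side[cand$a] %in% noninv) == (calls$side[cand$b] %in% noninv)
  ok <- ok & calls$side[cand$a] != calls$side[cand$b]
  ok <- ok & calls$chrom[cand$a] == calls$chrom[cand$b] &
    calls$chrom2[cand$a] == calls$chrom2[cand$b]
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(calls)
  d1 <- abs(calls$start[cand$a] - calls$start[cand$b])
  d2 <- abs(calls$pos2[cand$a] - calls$pos2[cand$b])
  cand$dist <- pmin(d1, d2) # distance on the insertion chromosome
  cand <- cand[cand$dist < z, , drop = FALSE]
  if (!nrow(cand)) return(calls)
  cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
  used <- logical(nrow(calls)); drop <- integer(0)
  for (k in seq_len(nrow(cand))) {
    a <- cand$a[k]; b <- cand$b[k]
    if (used[a] || used[b]) next
    used[a] <- TRUE; used[b] <- TRUE
    pa <- calls$precise[a]; pb <- calls$precise[b]
    base <- if (pb && !pa) b else a
    other <- if (base == a) b else a
    calls$pe_support[base] <- calls$pe_support[base] + calls$pe_support[other]
    calls$mapq_mean[base] <- mean(c(calls$mapq_mean[base], calls$mapq_mean[other]))
    calls$sr_support[base] <- na0(calls$sr_support[a]) + na0(calls$sr_support[b])
    calls$precise[base] <- pa || pb
    calls$pos2_b[base] <- calls$pos2[other]
    calls$merged_from[[base]] <- c(calls$call_id[a], calls$call_id[b])
    drop <- c(drop, other)
  }
  if (length(drop)) calls <- calls[-drop, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

## Assign final ids and the PASS/LowQual filter.
finalize_calls <- function(calls) {
  if (!nrow(calls)) {
    calls$id <- character(0); calls$filter <- character(0)
    return(calls)
  }
  calls <- calls[order(calls$chrom, calls$start, calls$sv_type), , drop = FALSE]
  cnt <- stats::ave(seq_len(nrow(calls)), calls$sv_type, FUN = seq_along)
  calls$id <- sprintf("%s%05d", calls$sv_type, cnt)
  calls$filter <- ifelse(calls$precise | (calls$pe_support >= 3 & calls$mapq_mean >= 20),
                         "PASS", "LowQual")
  rownames(calls) <- NULL
  calls
}

vcf_info <- function(call) {
  info <- c(
    if (call$precise) "PRECISE" else "IMPRECISE",
    sprintf("SVTYPE=%s", call$sv_type),
    if (call$sv_type != "TRA") sprintf("END=%d", as.integer(call$end)),
    if (call$sv_type != "TRA" && !is.na(call$sv_length)) sprintf("SVLEN=%d",
      as.integer(call$sv_length) * ifelse(call$sv_type == "DEL", -1L, 1L)),
    sprintf("PE=%d", as.integer(call$pe_support)),
    sprintf("MAPQ=%d", as.integer(round(call$mapq_mean))),
    if (!is.na(call$sr_support) && call$sr_support > 0) sprintf("SR=%d", as.integer(call$sr_support)),
    if (!is.na(call$srq)) sprintf("SRQ=%.4g", call$srq),
    if (!is.na(call$inslen) && call$inslen > 0) sprintf("INSLEN=%d", as.integer(call$inslen)),
    if (!is.na(call$ins_seq)) sprintf("INSSEQ=%s", call$ins_seq),
    if (!is.na(call$homlen) && call$homlen > 0) sprintf("HOMLEN=%d", as.integer(call$homlen)),
    if (!is.na(call$consensus)) sprintf("CONSENSUS=%s", call$consensus),
    if (!call$precise) sprintf("CIPOS=-%d,%d", as.integer(call$insert_max),
                               as.integer(call$insert_max)))
  paste(info, collapse = ";")
}

#' Write final SV calls as VCF (and optionally TSV)
#'
#' Emits VCF 4.2 with symbolic alternative alleles for deletions, tandem
#' duplications and inversions, and breakend (BND) record pairs for
#' translocations. Coordinates are 1-based in the output (internally the
#' package is 0-based half-open); record order is deterministic.
#'
#' @param calls finalised call table (see [sv_call()]).
#' @param path output VCF path.
#' @param genome optional named contig vector: adds contig headers and REF
#'   bases (otherwise REF is "N").
#' @param tsv optional path for a flat tab-separated mirror of the table.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, genome = NULL, tsv = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svdelver",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Tandem duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Split-read refined breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Paired-end interval only\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
    "##INFO=<ID=MAPQ,Number=1,Type=Integer,Description=\"Mean mapping quality of supporting pairs\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting split reads\">",
    "##INFO=<ID=SRQ,Number=1,Type=Float,Description=\"Split-read consensus alignment quality\">",
    "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Microinsertion length at breakpoint\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Microinsertion sequence\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length at breakpoint\">",
    "##INFO=<ID=CONSENSUS,Number=1,Type=String,Description=\"Split-read consensus sequence\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##FILTER=<ID=LowQual,Description=\"Imprecise call with weak paired-end support\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  refbase <- function(chrom, pos0) {
    if (is.null(genome)) return("N")
    b <- substr(genome[[chrom]], pos0 + 1L, pos0 + 1L)
    if (nzchar(b)) b else "N"
  }
  recs <- character(0)
  if (nrow(calls)) {
    for (r in seq_len(nrow(calls))) {
      call <- calls[r, ]
      info <- vcf_info(call)
      if (call$sv_type != "TRA") {
        recs <- c(recs, paste(
          call$chrom, call$start + 1L, call$id, refbase(call$chrom, call$start),
          sprintf("<%s>", call$sv_type), ".", call$filter, info, "GT", "./.",
          sep = "\t"))
      } else {
        ## breakend pair; bracket orientation by translocation class
        pa <- call$start + 1L; pb <- call$pos2 + 1L
        ra <- refbase(call$chrom, call$start); rb <- refbase(call$chrom2, call$pos2)
        alt <- switch(call$side %||% "TRA_1",
          TRA_1 = c(sprintf("%s[%s:%d[", ra, call$chrom2, pb),
                    sprintf("]%s:%d]%s", call$chrom, pa, rb)),
          TRA_2 = c(sprintf("%s]%s:%d]", ra, call$chrom2, pb),
                    sprintf("%s]%s:%d]", rb, call$chrom, pa)),
          TRA_3 = c(sprintf("]%s:%d]%s", call$chrom2, pb, ra),
                    sprintf("%s[%s:%d[", rb, call$chrom, pa)),
          TRA_4 = c(sprintf("[%s:%d[%s", call$chrom2, pb, ra),
                    sprintf("[%s:%d[%s", call$chrom, pa, rb)),
          c(sprintf("%s[%s:%d[", ra, call$chrom2, pb),
            sprintf("]%s:%d]%s", call$chrom, pa, rb)))
        id1 <- paste0(call$id, "_1"); id2 <- paste0(call$id, "_2")
        recs <- c(recs,
          paste(call$chrom, pa, id1, ra, alt[1], ".", call$filter,
                paste0(info, ";MATEID=", id2), "GT", "./.", sep = "\t"),
          paste(call$chrom2, pb, id2, rb, alt[2], ".", call$filter,
                paste0(info, ";MATEID=", id1), "GT", "./.", sep = "\t"))
      }
    }
  }
  writeLines(c(hdr, recs), path)
  if (!is.null(tsv)) {
    flat <- calls
    flat$members <- vapply(flat$members, function(m) paste(m, collapse = ","), character(1))
    flat$merged_from <- vapply(flat$merged_from, function(m) paste(m, collapse = ","), character(1))
    write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
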