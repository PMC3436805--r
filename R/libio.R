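#' Per-library insert-size profile
#'
#' Holds the paired-end insert size location/spread and the default pair
#' orientation of one sequencing library. The discordance cutoff is
#' `insert_max = median_insert + cutoff_sd * sd_insert`.
#'
#' @param median_insert median outer insert size (bp).
#' @param sd_insert insert size spread (bp), robustly estimated.
#' @param orientation default pair orientation: "FR", "RF" or "FF_like".
#' @param cutoff_sd discordance cutoff in units of `sd_insert` (default 3).
#' @param library_id library name.
#' @return an object of class `library_profile`.
#' @export
library_profile <- function(median_insert, sd_insert, orientation = "FR",
                            cutoff_sd = 3, library_id = "lib1") {
  stopifnot(sd_insert >= 0, orientation %in% c("FR", "RF", "FF_like"))
  structure(list(
    library_id = library_id,
    median_insert = median_insert,
    sd_insert = sd_insert,
    orientation = orientation,
    cutoff_sd = cutoff_sd,
    insert_max = median_insert + cutoff_sd * sd_insert
  ), class = "library_profile")
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf("library '%s': %s, insert median %.1f, sd %.1f, discordance cutoff %.1f bp\n",
              x$library_id, x$orientation, x$median_insert, x$sd_insert, x$insert_max))
  invisible(x)
}

## Positional orientation of mapped same-chromosome pairs:
## strand of leftmost then rightmost read.
pair_orientation <- function(s_left, s_right) {
  ifelse(s_left == "+" & s_right == "-", "FR",
         ifelse(s_left == "-" & s_right == "+", "RF", "FF_like"))
}

#' Estimate a library's insert-size profile from its alignments
#'
#' Samples properly paired alignments (both mates mapped to one chromosome),
#' takes the modal relative orientation as the library default, and estimates
#' the outer insert size median and spread over pairs with that orientation.
#' The spread is the scaled median absolute deviation (consistent with the
#' Normal standard deviation), which is insensitive to the SV-spanning
#' outliers the caller is after.
#'
#' @param pairs an `sv_pairs` data.frame (see [project_alignments()] or
#'   [read_alignments()]).
#' @param sample_size number of proper pairs profiled.
#' @param cutoff_sd discordance cutoff multiplier.
#' @param min_pairs minimum proper pairs required.
#' @return a [library_profile()].
#' @export
estimate_library_profile <- function(pairs, sample_size = 10000L, cutoff_sd = 3,
                                     min_pairs = 1000L) {
  lib <- pairs$library_id[1] %||% "lib1"
  ok <- pairs$mapped1 & pairs$mapped2 & pairs$chrom1 == pairs$chrom2
  sub <- pairs[ok, , drop = FALSE]
  if (nrow(sub) < min_pairs)
    stop(sprintf("library '%s': only %d proper pairs, need >= %d for profiling",
                 lib, nrow(sub), min_pairs))
  sub <- head(sub, sample_size)
  left1 <- sub$pos1 <= sub$pos2
  s_left <- ifelse(left1, sub$strand1, sub$strand2)
  s_right <- ifelse(left1, sub$strand2, sub$strand1)
  ori <- pair_orientation(s_left, s_right)
  tab <- table(factor(ori, levels = c("FR", "RF", "FF_like")))
  orientation <- names(tab)[which.max(tab)] # ties resolve to FR (first level)
  insert <- pmax(sub$end1, sub$end2) - pmin(sub$pos1, sub$pos2)
  insert <- insert[ori == orientation]
  med <- median(insert)
  sdv <- mad(insert, center = med)
  library_profile(med, sdv, orientation, cutoff_sd, lib)
}

## Normalise mate order so (chrom_a, a_start) <= (chrom_b, b_start),
## chromosomes compared lexicographically. Returns normalised columns.
normalize_pairs <- function(pairs) {
  swap <- (pairs$chrom1 > pairs$chrom2) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  pick <- function(a, b) ifelse(swap, b, a)
  data.frame(
    chrom_a = pick(pairs$chrom1, pairs$chrom2),
    a_start = pick(pairs$pos1, pairs$pos2),
    a_end = pick(pairs$end1, pairs$end2),
    strand_a = pick(pairs$strand1, pairs$strand2),
    chrom_b = pick(pairs$chrom2, pairs$chrom1),
    b_start = pick(pairs$pos2, pairs$pos1),
    b_end = pick(pairs$end2, pairs$end1),
    strand_b = pick(pairs$strand2, pairs$strand1),
    stringsAsFactors = FALSE)
}

## Vectorised SV-signature classification of normalised mapped pairs.
classify_normalized <- function(np, profile) {
  def_left <- switch(profile$orientation, FR = "+", RF = "-",
                     stop("cannot classify pairs for an FF_like library"))
  def_right <- if (def_left == "+") "-" else "+"
  same <- np$chrom_a == np$chrom_b
  insert <- np$b_end - np$a_start
  sig <- rep("CONCORDANT", nrow(np))
  default_ori <- np$strand_a == def_left & np$strand_b == def_right
  sig[same & default_ori & insert > profile$insert_max] <- "DEL"
  sig[same & np$strand_a == def_right & np$strand_b == def_left] <- "DUP"
  sig[same & np$strand_a == def_left & np$strand_b == def_left] <- "INV_LEFT"
  sig[same & np$strand_a == def_right & np$strand_b == def_right] <- "INV_RIGHT"
  tra_code <- 1L + 2L * (np$strand_a == "-") + (np$strand_a == np$strand_b)
  ## codes: (+,-)=1, (+,+)=2, (-,+)=3, (-,-)=4
  sig[!same] <- paste0("TRA_", tra_code[!same])
  sig
}

#' Classify a mapped read pair against its library profile
#'
#' Assigns the paired-end SV signature: `DEL` for default-orientation pairs
#' whose outer insert exceeds the library cutoff, `DUP` for pairs whose mates
#' swapped relative order (strands kept), `INV_LEFT`/`INV_RIGHT` for
#' same-strand pairs by spanning side, `TRA_1..4` for interchromosomal pairs
#' keyed by the normalised strand combination, and `CONCORDANT` otherwise.
#'
#' @param pair a one-row `sv_pairs`-shaped data.frame (both mates mapped).
#' @param profile the pair's [library_profile()].
#' @return a single signature string.
#' @export
classify_pair <- function(pair, profile) {
  np <- normalize_pairs(pair)
  classify_normalized(np, profile)[1L]
}

#' Extract and classify discordant read pairs across libraries
#'
#' Filters to uniquely mapping pairs (both mates mapped with mapping quality
#' at or above `map_qual`), classifies each against its own library profile,
#' keeps non-concordant pairs, normalises mate order, and returns the joint
#' list binned by chromosome (pair of chromosomes for translocations) and
#' sorted by left-most alignment position.
#'
#' @param pairs_list one `sv_pairs` data.frame per library (a bare data.frame
#'   is treated as a single library), named by library.
#' @param profiles list of [library_profile()]s, parallel to `pairs_list`.
#' @param map_qual minimum per-mate mapping quality ("uniquely mapping").
#' @return an `sv_discordant` data.frame: normalised coordinates, signature,
#'   library id, minimum mapping quality and the library's insert cutoff.
#' @export
extract_discordant <- function(pairs_list, profiles, map_qual = 1L) {
  if (is.data.frame(pairs_list)) pairs_list <- list(pairs_list)
  if (inherits(profiles, "library_profile")) profiles <- list(profiles)
  stopifnot(length(pairs_list) == length(profiles))
  out <- vector("list", length(pairs_list))
  for (k in seq_along(pairs_list)) {
    p <- pairs_list[[k]]; prof <- profiles[[k]]
    keep <- p$mapped1 & p$mapped2 & pmin(p$mapq1, p$mapq2) >= map_qual
    p <- p[keep, , drop = FALSE]
    if (!nrow(p)) next
    np <- normalize_pairs(p)
    sig <- classify_normalized(np, prof)
    disc <- sig != "CONCORDANT"
    if (!any(disc)) next
    np <- np[disc, , drop = FALSE]
    np$signature <- sig[disc]
    np$mapq <- pmin(p$mapq1, p$mapq2)[disc]
    np$library_id <- prof$library_id
    np$insert_max <- prof$insert_max
    np$sd_insert <- prof$sd_insert
    out[[k]] <- np
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    d <- data.frame(chrom_a = character(0), a_start = integer(0), a_end = integer(0),
                    strand_a = character(0), chrom_b = character(0), b_start = integer(0),
                    b_end = integer(0), strand_b = character(0), signature = character(0),
                    mapq = integer(0), library_id = character(0), insert_max = numeric(0),
                    sd_insert = numeric(0), pair_id = integer(0))
    class(d) <- c("sv_discordant", "data.frame")
    return(d)
  }
  d <- do.call(rbind, out)
  ord <- order(d$chrom_a, d$chrom_b, d$a_start, d$b_start)
  d <- d[ord, , drop = FALSE]
  d$pair_id <- seq_len(nrow(d))
  rownames(d) <- NULL
  class(d) <- c("sv_discordant", "data.frame")
  d
}

## ---- SAM/BAM interface ------------------------------------------------------

cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    w[ok] <- vapply(regmatches(cigar[ok], gregexpr("\\d+[MDN=X]", cigar[ok])), function(ops) {
      if (!length(ops)) return(0L)
      sum(as.integer(sub("[MDN=X]", "", ops)))
    }, integer(1))
  }
  w
}

#' Read paired alignments from an indexed BAM file
#'
#' Loads primary alignments (secondary, supplementary and duplicate-flagged
#' records are ignored), pairs mates by name, and returns the package's
#' pair-level table. Sequences are retained for unmapped mates so they can be
#' used as split-read candidates.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param library_id library name for the file (one file = one library).
#' @return an `sv_pairs` data.frame.
#' @export
read_alignments <- function(bam, library_id = basename(bam)) {
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam)
  flg <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE,
                                isDuplicate = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flg,
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq", "seq"))
  res <- Rsamtools::scanBam(bam, param = par)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    pr <- data.frame(pair_id = integer(0), library_id = character(0),
                     chrom1 = character(0), pos1 = integer(0), end1 = integer(0),
                     strand1 = character(0), mapped1 = logical(0), mapq1 = integer(0),
                     chrom2 = character(0), pos2 = integer(0), end2 = integer(0),
                     strand2 = character(0), mapped2 = logical(0), mapq2 = integer(0),
                     clip1 = integer(0), clip2 = integer(0),
                     seq1 = character(0), seq2 = character(0), stringsAsFactors = FALSE)
    class(pr) <- c("sv_pairs", "data.frame")
    return(pr)
  }
  first <- bitwAnd(res$flag, 64L) > 0L
  unmapped <- bitwAnd(res$flag, 4L) > 0L
  rw <- cigar_ref_width(res$cigar)
  ## restore sequencing direction for minus-strand mapped records
  seqs <- as.character(res$seq)
  neg <- !unmapped & as.character(res$strand) == "-"
  seqs[neg] <- revcomp(seqs[neg])
  res$seq <- seqs
  qw <- nchar(seqs)
  clip <- ifelse(unmapped, 0L, qw - rw) # idealised: clipped bases = query minus ref span
  rec <- data.frame(
    qname = res$qname,
    chrom = as.character(res$rname),
    pos = ifelse(unmapped, NA_integer_, res$pos - 1L), # to 0-based
    end = ifelse(unmapped, NA_integer_, res$pos - 1L + rw),
    strand = as.character(res$strand),
    mapped = !unmapped,
    mapq = ifelse(unmapped, 0L, res$mapq),
    clip = clip,
    seq = as.character(res$seq),
    first = first, stringsAsFactors = FALSE)
  r1 <- rec[rec$first, , drop = FALSE]
  r2 <- rec[!rec$first, , drop = FALSE]
  idx <- match(r1$qname, r2$qname)
  ok <- !is.na(idx)
  r1 <- r1[ok, , drop = FALSE]; r2 <- r2[idx[ok], , drop = FALSE]
  pr <- data.frame(
    pair_id = seq_len(nrow(r1)), library_id = library_id,
    chrom1 = r1$chrom, pos1 = r1$pos, end1 = r1$end, strand1 = r1$strand,
    mapped1 = r1$mapped, mapq1 = r1$mapq,
    chrom2 = r2$chrom, pos2 = r2$pos, end2 = r2$end, strand2 = r2$strand,
    mapped2 = r2$mapped, mapq2 = r2$mapq,
    clip1 = r1$clip, clip2 = r2$clip,
    seq1 = ifelse(r1$mapped & r1$clip == 0L, NA_character_, r1$seq),
    seq2 = ifelse(r2$mapped & r2$clip == 0L, NA_character_, r2$seq),
    stringsAsFactors = FALSE)
  ## unmapped mates carry the mapped mate's coordinates in SAM; strip them
  pr$pos1[!pr$mapped1] <- NA_integer_; pr$end1[!pr$mapped1] <- NA_integer_
  pr$pos2[!pr$mapped2] <- NA_integer_; pr$end2[!pr$mapped2] <- NA_integer_
  class(pr) <- c("sv_pairs", "data.frame")
  pr
}

#' Write a simulation's projected alignments as a sorted, indexed BAM
#'
#' Materialises every read sequence, emits SAM records mirroring the
#' idealised projection (unmapped junction reads become unmapped records
#' placed at their mapped mate), converts to BAM, sorts and indexes.
#'
#' @param sim an `sv_sim` object.
#' @param pairs the matching [project_alignments()] table.
#' @param path output BAM path (".bam" appended if missing).
#' @return the BAM path.
#' @export
write_bam <- function(sim, pairs, path) {
  rl <- sim$params$read_len
  ref_len <- vapply(sim$reference, nchar, integer(1))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_len), ref_len))
  n <- nrow(pairs)
  qual <- strrep("I", rl)
  recs <- character(2L * n)
  for (mate in 1:2) {
    gidx <- 2L * (pairs$pair_id - 1L) + mate
    seqs <- sim_read_seq(sim, gidx)
    m <- if (mate == 1L) pairs[, c("chrom1", "pos1", "strand1", "mapped1", "mapq1")] else
      pairs[, c("chrom2", "pos2", "strand2", "mapped2", "mapq2")]
    names(m) <- c("chrom", "pos", "strand", "mapped", "mapq")
    o <- if (mate == 1L) pairs[, c("chrom2", "pos2", "strand2", "mapped2")] else
      pairs[, c("chrom1", "pos1", "strand1", "mapped1")]
    names(o) <- c("chrom", "pos", "strand", "mapped")
    flag <- 1L + 64L * (mate == 1L) + 128L * (mate == 2L) +
      4L * (!m$mapped) + 8L * (!o$mapped) +
      16L * (m$mapped & m$strand == "-") + 32L * (o$mapped & o$strand == "-")
    ## SAM convention: an unmapped read is placed at its mapped mate
    chrom <- ifelse(m$mapped, m$chrom, o$chrom)
    pos1 <- ifelse(m$mapped, m$pos, o$pos) + 1L
    mchrom <- ifelse(o$mapped, o$chrom, m$chrom)
    mpos1 <- ifelse(o$mapped, o$pos, m$pos) + 1L
    ## SAM stores mapped "-" reads reverse-complemented (reference forward);
    ## unmapped reads keep their sequencing direction
    flipped <- m$mapped & m$strand == "-"
    seqs[flipped] <- revcomp(seqs[flipped])
    pos1[is.na(pos1)] <- 1L; mpos1[is.na(mpos1)] <- 1L
    recs[seq(mate, 2L * n, by = 2L)] <- paste(
      sprintf("pair%d", pairs$pair_id), flag, chrom, pos1,
      ifelse(m$mapped, m$mapq, 0L),
      ifelse(m$mapped, sprintf("%dM", rl), "*"),
      ifelse(mchrom == chrom, "=", mchrom), mpos1, 0L, seqs, qual,
      sep = "\t")
  }
  sam <- tempfile(fileext = ".sam")
  writeLines(c(hdr, recs), sam)
  if (!grepl("\\.bam$", path)) path <- paste0(path, ".bam")
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}
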