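#' Generate a seeded random reference sequence
#'
#' Draws a uniform random A/C/G/T sequence of the requested length. Used as a
#' repeat-free stand-in for a real genomic region so the full caller can be
#' exercised without external data.
#'
#' @param length sequence length in bp (> 0).
#' @param seed optional integer seed; when given the draw is deterministic.
#' @param chrom contig name.
#' @return named character vector of length one (the contig).
#' @export
generate_reference <- function(length, seed = NULL, chrom = "chrA") {
  if (length <= 0L) stop("reference length must be positive")
  if (!is.null(seed)) set.seed(seed)
  codes <- c(65L, 67L, 71L, 84L) # A C G T
  seq <- rawToChar(as.raw(codes[sample.int(4L, length, replace = TRUE)]))
  stats::setNames(seq, chrom)
}

## Cumulative-shift map from source coordinates to post-excision main-chromosome
## coordinates (translocated segments are removed from the main contig).
## Only segments ending at or before p shift it; a position at a segment start
## (the insertion point) keeps its own segment's length.
make_shift <- function(tra_start, tra_len) {
  tra_end <- tra_start + tra_len
  cum <- c(0, cumsum(tra_len))
  function(p) p - cum[findInterval(p, tra_end) + 1L]
}

#' Plant structural variants into a reference sequence
#'
#' Places non-overlapping deletions, tandem duplications, inversions and
#' translocated segments into a source contig. Deletions remove the segment,
#' duplications double it in place, inversions reverse-complement it in place.
#' Translocated segments stay in place in the donor (the sequence reads are
#' sampled from) but are excised from the calling reference and appended as
#' separate contigs, so read pairs spanning the segment ends map
#' interchromosomally.
#'
#' @param reference named character vector of length one (the source contig),
#'   e.g. from [generate_reference()].
#' @param n_sv named integer vector of event counts, names among
#'   `DEL`, `DUP`, `INV`, `TRA`.
#' @param size_range length-2 numeric, uniform SV size bounds in bp.
#' @param seed optional integer seed.
#' @param margin minimum distance of any event from the contig ends (bp).
#' @param max_tries placement retries before giving up.
#' @return list with elements `reference` (named character vector: the calling
#'   reference, with translocated segments as extra contigs), `donor` (single
#'   character string the reads are sampled from), `blocks` (donor-to-reference
#'   collinear block table), and `truth` (one row per planted event, 0-based
#'   half-open coordinates on the calling reference).
#' @export
plant_variants <- function(reference, n_sv, size_range = c(500, 5000),
                           seed = NULL, margin = 2000L, max_tries = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(reference) == 1L, !is.null(names(reference)))
  src <- reference[[1L]]
  main <- names(reference)[1L]
  L <- nchar(src)
  n_sv <- n_sv[n_sv > 0]
  types <- rep(names(n_sv), n_sv)
  n <- length(types)
  if (n == 0L) { # SV-free genome (null simulation)
    return(list(
      reference = stats::setNames(src, main),
      donor = src,
      blocks = data.frame(d_start = 0L, d_end = L, chrom = main,
                          r_start = 0L, r_end = L, strand = "+",
                          stringsAsFactors = FALSE),
      truth = data.frame(id = character(0), sv_type = character(0),
                         chrom = character(0), start = integer(0), end = integer(0),
                         size = integer(0), chrom2 = character(0),
                         pos2_start = integer(0), pos2_end = integer(0),
                         src_start = integer(0), src_end = integer(0),
                         stringsAsFactors = FALSE)))
  }
  sizes <- as.integer(round(runif(n, size_range[1L], size_range[2L])))
  if (10 * max(sizes) > L) stop("reference too short for requested SV sizes")
  if (sum(sizes) > 0.5 * L) stop("planted footprint exceeds half the reference")
  if (is.null(max_tries)) max_tries <- 1000L * n

  starts <- integer(0); ends <- integer(0)
  order_idx <- sample.int(n) # interleave types randomly
  placed_type <- character(0); placed_size <- integer(0)
  tries <- 0L
  for (i in order_idx) {
    sz <- sizes[i]
    repeat {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place non-overlapping events: increase reference length or reduce counts")
      s <- as.integer(floor(runif(1, margin, L - margin - sz)))
      if (all(s + sz <= starts | s >= ends)) break
    }
    starts <- c(starts, s); ends <- c(ends, s + sz)
    placed_type <- c(placed_type, types[i]); placed_size <- c(placed_size, sz)
  }
  ord <- order(starts)
  ev <- data.frame(type = placed_type[ord], start = starts[ord], end = ends[ord],
                   size = placed_size[ord], stringsAsFactors = FALSE)

  tra <- ev[ev$type == "TRA", , drop = FALSE]
  shift <- make_shift(tra$start, tra$end - tra$start)
  tra_contig <- if (nrow(tra)) sprintf("chrT%d", seq_len(nrow(tra))) else character(0)

  ## calling reference: main contig minus TRA segments, plus segment contigs
  if (nrow(tra)) {
    keep <- c(0L, as.vector(rbind(tra$start, tra$end)), L)
    pieces <- character(0)
    for (k in seq(1, length(keep) - 1, by = 2))
      pieces <- c(pieces, substr(src, keep[k] + 1L, keep[k + 1L]))
    ref <- c(paste(pieces, collapse = ""),
             vapply(seq_len(nrow(tra)),
                    function(k) substr(src, tra$start[k] + 1L, tra$end[k]),
                    character(1)))
    names(ref) <- c(main, tra_contig)
  } else {
    ref <- stats::setNames(src, main)
  }

  ## donor emission: list of (src_start, src_end, strand) pieces
  piece <- list(); cursor <- 0L
  emit <- function(s, e, strand = "+") piece[[length(piece) + 1L]] <<- c(s, e, as.integer(strand == "-"))
  for (k in seq_len(nrow(ev))) {
    if (ev$start[k] > cursor) emit(cursor, ev$start[k])
    switch(ev$type[k],
      DEL = NULL,
      DUP = { emit(ev$start[k], ev$end[k]); emit(ev$start[k], ev$end[k]) },
      INV = emit(ev$start[k], ev$end[k], "-"),
      TRA = emit(ev$start[k], ev$end[k]))
    cursor <- ev$end[k]
  }
  if (cursor < L) emit(cursor, L)
  pm <- do.call(rbind, piece)
  p_start <- as.integer(pm[, 1L]); p_end <- as.integer(pm[, 2L])
  p_minus <- pm[, 3L] == 1

  ## map each piece to calling-reference coordinates
  in_tra <- rep(NA_integer_, length(p_start))
  if (nrow(tra))
    for (k in seq_len(nrow(tra)))
      in_tra[p_start >= tra$start[k] & p_end <= tra$end[k]] <- k
  b_chrom <- ifelse(is.na(in_tra), main, tra_contig[in_tra])
  b_rs <- ifelse(is.na(in_tra), shift(p_start), p_start - tra$start[in_tra])
  b_re <- b_rs + (p_end - p_start)
  b_strand <- ifelse(p_minus, "-", "+")

  ## merge collinear-contiguous neighbours (e.g. flank + first duplication copy)
  keep_row <- rep(TRUE, length(p_start))
  for (k in seq_along(p_start)[-1]) {
    j <- max(which(keep_row[seq_len(k - 1L)]))
    if (b_strand[k] == "+" && b_strand[j] == "+" &&
        b_chrom[k] == b_chrom[j] && b_rs[k] == b_re[j]) {
      b_re[j] <- b_re[k]; p_end[j] <- p_end[j] + (p_end[k] - p_start[k])
      keep_row[k] <- FALSE
    }
  }
  lens <- (b_re - b_rs)[keep_row]
  d_end <- cumsum(lens)
  blocks <- data.frame(
    d_start = d_end - lens, d_end = d_end,
    chrom = b_chrom[keep_row], r_start = b_rs[keep_row], r_end = b_re[keep_row],
    strand = b_strand[keep_row], stringsAsFactors = FALSE)

  donor_pieces <- vapply(which(keep_row), function(k) {
    s <- substr(src, p_start[k] + 1L, p_end[k])
    if (p_minus[k]) revcomp(s) else s
  }, character(1))
  ## careful: merged rows extended p_end above, so substr uses updated bounds
  donor <- paste(donor_pieces, collapse = "")

  ## truth table in calling-reference coordinates
  is_tra <- ev$type == "TRA"
  tra_idx <- cumsum(is_tra)
  truth <- data.frame(
    id = sprintf("%s%04d", ev$type, seq_len(nrow(ev))),
    sv_type = ev$type,
    chrom = main,
    start = ifelse(is_tra, shift(ev$start), shift(ev$start)),
    end = ifelse(is_tra, shift(ev$start), shift(ev$end)),
    size = ev$size,
    chrom2 = ifelse(is_tra, tra_contig[pmax(tra_idx, 1L)], NA_character_),
    pos2_start = ifelse(is_tra, 0L, NA_integer_),
    pos2_end = ifelse(is_tra, ev$size, NA_integer_),
    src_start = ev$start, src_end = ev$end,
    stringsAsFactors = FALSE)

  list(reference = ref, donor = donor, blocks = blocks, truth = truth)
}

#' Simulate error-bearing paired-end reads from a donor sequence
#'
#' Fragment lengths are Normal(insert_mean, insert_sd), truncated at twice the
#' read length; fragment starts are uniform; orientation is FR (forward first
#' mate, reverse-complemented second mate). Substitution errors are i.i.d. per
#' base. Sequences are materialised lazily (see [sim_read_seq()]); this returns
#' only coordinates and the error table.
#'
#' @param donor_len donor sequence length (bp).
#' @param coverage haploid sequence coverage; the number of pairs is
#'   `round(coverage * donor_len / (2 * read_len))`.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd outer insert (fragment) size distribution (bp).
#' @param error_rate per-base substitution probability.
#' @return list with `reads` (data.frame: `frag_start`, `frag_len`) and
#'   `errors` (data.frame: global read index, position in read, base shift).
#' @export
simulate_reads <- function(donor_len, coverage = 15, read_len = 75L,
                           insert_mean = 300, insert_sd = 30, error_rate = 0.01) {
  if (donor_len <= 0L) stop("donor is empty")
  if (insert_mean < 2 * read_len) stop("insert mean must be at least twice the read length")
  n_pairs <- as.integer(round(coverage * donor_len / (2 * read_len)))
  fl <- pmax(2L * read_len, as.integer(round(rnorm(n_pairs, insert_mean, insert_sd))))
  fl <- pmin(fl, donor_len)
  fs <- as.integer(floor(runif(n_pairs, 0, donor_len - fl + 1)))
  total <- 2 * n_pairs * read_len
  n_err <- if (error_rate > 0) rbinom(1L, total, error_rate) else 0L
  if (n_err > 0L) {
    idx <- sort(sample.int(total, n_err))
    errors <- data.frame(read = (idx - 1L) %/% read_len + 1L,
                         pos = (idx - 1L) %% read_len + 1L,
                         shift = sample.int(3L, n_err, replace = TRUE))
  } else {
    errors <- data.frame(read = integer(0), pos = integer(0), shift = integer(0))
  }
  list(reads = data.frame(frag_start = fs, frag_len = fl), errors = errors)
}

#' Simulate a structural-variant study: reference, planted events, reads
#'
#' One-stop generator for the simulation study design: a seeded random
#' reference, non-overlapping planted SVs, and FR paired reads with i.i.d.
#' substitution errors. Defaults mirror the benchmark's default cell
#' (15x coverage, 75 bp reads, Normal(300, 30) inserts, 1% error).
#'
#' @param genome_length source contig length (bp); ignored when `reference`
#'   is supplied.
#' @param n_sv named counts of events to plant (names among DEL/DUP/INV/TRA).
#' @param size_range SV size bounds in bp.
#' @param coverage,read_len,insert_mean,insert_sd,error_rate read simulation
#'   parameters, see [simulate_reads()].
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param reference optional user-supplied named character contig to plant
#'   into, instead of a random draw.
#' @param margin minimum event distance from contig ends (bp).
#' @return an object of class `sv_sim`: reference, donor, block map, truth
#'   table, read coordinates, error table and parameters.
#' @export
sv_simulate <- function(genome_length = 5e6, n_sv = c(DEL = 50),
                        size_range = c(500, 5000), coverage = 15,
                        read_len = 75L, insert_mean = 300, insert_sd = 30,
                        error_rate = 0.01, seed = 1L, reference = NULL,
                        margin = 2000L) {
  set.seed(seed)
  if (is.null(reference)) {
    reference <- generate_reference(genome_length)
  }
  planted <- plant_variants(reference, n_sv = n_sv, size_range = size_range,
                            margin = margin)
  rd <- simulate_reads(nchar(planted$donor), coverage = coverage,
                       read_len = read_len, insert_mean = insert_mean,
                       insert_sd = insert_sd, error_rate = error_rate)
  structure(list(
    reference = planted$reference,
    donor = planted$donor,
    blocks = planted$blocks,
    truth = planted$truth,
    reads = rd$reads,
    errors = rd$errors,
    params = list(coverage = coverage, read_len = read_len,
                  insert_mean = insert_mean, insert_sd = insert_sd,
                  error_rate = error_rate, seed = seed,
                  size_range = size_range, n_sv = n_sv)
  ), class = "sv_sim")
}

#' @export
print.sv_sim <- function(x, ...) {
  cat(sprintf("sv_sim: %d contig(s), donor %d bp, %d planted events, %d read pairs (seed %d)\n",
              length(x$reference), nchar(x$donor), nrow(x$truth),
              nrow(x$reads), x$params$seed))
  print(table(x$truth$sv_type))
  invisible(x)
}

## Donor-frame coordinates of one mate. Mate 1 sits at the fragment start on
## the donor forward strand; mate 2 at the fragment end, sequenced reverse.
mate_coords <- function(sim, mate) {
  rl <- sim$params$read_len
  if (mate == 1L) {
    list(start = sim$reads$frag_start, strand = "+")
  } else {
    list(start = sim$reads$frag_start + sim$reads$frag_len - rl, strand = "-")
  }
}

#' Materialise simulated read sequences
#'
#' Returns the read sequences as sequenced (mate 2 reverse-complemented),
#' with substitution errors applied. Global read index convention:
#' read `2*(pair-1) + mate`.
#'
#' @param sim an `sv_sim` object.
#' @param read_idx integer vector of global read indices.
#' @return character vector of read sequences.
#' @export
sim_read_seq <- function(sim, read_idx) {
  rl <- sim$params$read_len
  pair <- (read_idx + 1L) %/% 2L
  mate <- 2L - (read_idx %% 2L)
  fs <- sim$reads$frag_start[pair]
  fl <- sim$reads$frag_len[pair]
  d_start <- ifelse(mate == 1L, fs, fs + fl - rl)
  seqs <- substring(sim$donor, d_start + 1L, d_start + rl)
  rev_sel <- mate == 2L
  if (any(rev_sel)) seqs[rev_sel] <- revcomp(seqs[rev_sel])
  ## apply substitution errors (positions are in sequencing direction)
  err <- sim$errors[sim$errors$read %in% read_idx, , drop = FALSE]
  if (nrow(err)) {
    where <- match(err$read, read_idx)
    for (k in seq_len(nrow(err))) {
      i <- where[k]; p <- err$pos[k]
      orig <- substr(seqs[i], p, p)
      code <- match(orig, DNA_BASES)
      if (!is.na(code))
        substr(seqs[i], p, p) <- DNA_BASES[((code - 1L + err$shift[k]) %% 4L) + 1L]
    }
  }
  seqs
}

## Vectorised donor->reference liftover of reads of fixed length rl.
## A read is mapped when it fits one collinear block with at most `margin`
## bp of overhang; otherwise it crosses an SV junction and is unmapped.
lift_reads <- function(d_start, rl, blocks, ref_len, margin = 5L) {
  nb <- nrow(blocks)
  b <- findInterval(d_start, blocks$d_start)
  over_right <- d_start + rl - blocks$d_end[b]
  in_b1 <- blocks$d_end[b] - d_start
  use_next <- over_right > margin & in_b1 <= margin & b < nb
  b[use_next] <- b[use_next] + 1L
  ov_r <- d_start + rl - blocks$d_end[b]
  ov_l <- blocks$d_start[b] - d_start
  mapped <- ov_r <= margin & ov_l <= margin
  plus <- blocks$strand[b] == "+"
  pos <- ifelse(plus,
                blocks$r_start[b] + (d_start - blocks$d_start[b]),
                blocks$r_start[b] + (blocks$d_end[b] - (d_start + rl)))
  chrom <- blocks$chrom[b]
  pos <- pmax(pos, 0L)
  pos <- pmin(pos, ref_len[chrom] - rl)
  list(chrom = chrom, pos = as.integer(pos), flip = !plus, mapped = mapped,
       block = b, in_block = pmin(d_start + rl, blocks$d_end[b]) - pmax(d_start, blocks$d_start[b]))
}

#' Project simulated reads onto the calling reference (idealised alignment)
#'
#' Exact truth lift-over standing in for a read aligner: a read lying wholly
#' inside one collinear donor-reference block (up to `margin` bp of junction
#' overhang) is emitted as mapped at its lifted coordinate; a read crossing an
#' SV junction by more than `margin` bp is emitted unmapped (its sequence is
#' materialised so it can serve as a split-read candidate). Pairs spanning an
#' SV become discordant automatically by construction.
#'
#' @param sim an `sv_sim` object.
#' @param margin junction overhang (bp) still tolerated for a mapped read.
#' @param mapq mapping quality assigned to mapped reads.
#' @param softclip also emit junction-crossing reads as soft-clipped mapped
#'   reads (clipped at the junction) instead of unmapped.
#' @param check_unique when TRUE, reads whose sequence occurs more than once
#'   in the reference (exact search, either strand) get mapping quality 0.
#' @param library_id library name recorded on every pair.
#' @return a `sv_pairs` data.frame, one row per read pair, with per-mate
#'   reference coordinates (0-based half-open), strands, mapped flags, mapping
#'   qualities, soft-clip lengths and (for unmapped or clipped mates) the read
#'   sequence.
#' @export
project_alignments <- function(sim, margin = 5L, mapq = 60L, softclip = FALSE,
                               check_unique = FALSE, library_id = "lib1") {
  rl <- sim$params$read_len
  ref_len <- vapply(sim$reference, nchar, integer(1))
  n <- nrow(sim$reads)
  m1 <- mate_coords(sim, 1L); m2 <- mate_coords(sim, 2L)
  L1 <- lift_reads(m1$start, rl, sim$blocks, ref_len, margin)
  L2 <- lift_reads(m2$start, rl, sim$blocks, ref_len, margin)
  ## donor strands: mate1 "+", mate2 "-"; block flip inverts
  s1 <- ifelse(L1$flip, "-", "+")
  s2 <- ifelse(L2$flip, "+", "-")
  pr <- data.frame(
    pair_id = seq_len(n), library_id = library_id,
    chrom1 = L1$chrom, pos1 = L1$pos, end1 = L1$pos + rl, strand1 = s1,
    mapped1 = L1$mapped, mapq1 = ifelse(L1$mapped, mapq, 0L),
    chrom2 = L2$chrom, pos2 = L2$pos, end2 = L2$pos + rl, strand2 = s2,
    mapped2 = L2$mapped, mapq2 = ifelse(L2$mapped, mapq, 0L),
    clip1 = 0L, clip2 = 0L,
    seq1 = NA_character_, seq2 = NA_character_,
    stringsAsFactors = FALSE)

  handle_unmapped <- function(pr, Lx, mate) {
    un <- which(!Lx$mapped)
    if (!length(un)) return(pr)
    gidx <- 2L * (un - 1L) + mate
    seqs <- sim_read_seq(sim, gidx)
    if (softclip) {
      keep_len <- Lx$in_block[un]
      clip <- rl - keep_len
      if (mate == 1L) {
        pr$mapped1[un] <- TRUE; pr$clip1[un] <- clip
        pr$end1[un] <- pr$pos1[un] + rl; pr$seq1[un] <- seqs
        pr$mapq1[un] <- mapq
      } else {
        pr$mapped2[un] <- TRUE; pr$clip2[un] <- clip
        pr$end2[un] <- pr$pos2[un] + rl; pr$seq2[un] <- seqs
        pr$mapq2[un] <- mapq
      }
    } else {
      if (mate == 1L) pr$seq1[un] <- seqs else pr$seq2[un] <- seqs
    }
    pr
  }
  pr <- handle_unmapped(pr, L1, 1L)
  pr <- handle_unmapped(pr, L2, 2L)

  ## internal consistency guard: unmapped reads must overlap a junction
  bad <- (!pr$mapped1 & L1$in_block >= rl) | (!pr$mapped2 & L2$in_block >= rl)
  if (any(bad)) stop("simulator inconsistency: unliftable read with no junction explanation")

  if (check_unique) {
    gidx <- seq_len(2L * n)
    seqs <- sim_read_seq(sim, gidx)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
    subj <- Biostrings::DNAStringSet(sim$reference)
    cnt <- rowSums(Biostrings::vcountPDict(pd, subj)) +
      rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(subj)))
    multi <- cnt > 1L
    pr$mapq1[multi[seq(1L, 2L * n, by = 2L)]] <- 0L
    pr$mapq2[multi[seq(2L, 2L * n, by = 2L)]] <- 0L
  }
  class(pr) <- c("sv_pairs", "data.frame")
  pr
}

#' Write simulated reads as paired FASTQ files
#' @param sim an `sv_sim` object.
#' @param file1,file2 output FASTQ paths for mate 1 and mate 2.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(sim, file1, file2) {
  n <- nrow(sim$reads)
  rl <- sim$params$read_len
  qual <- strrep("I", rl)
  for (mate in 1:2) {
    gidx <- 2L * (seq_len(n) - 1L) + mate
    seqs <- sim_read_seq(sim, gidx)
    lines <- as.vector(rbind(sprintf("@pair%d/%d", seq_len(n), mate), seqs, "+", qual))
    writeLines(lines, if (mate == 1L) file1 else file2)
  }
  invisible(c(file1, file2))
}
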