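#' Call structural variants from paired-end alignments
#'
#' End-to-end caller: estimates per-library insert profiles (unless given),
#' extracts and classifies discordant pairs jointly across libraries,
#' clusters them per signature into imprecise paired-end calls, refines each
#' call to single-nucleotide breakpoints with split reads, and merges
#' complementary inversion and translocation junction calls.
#'
#' @param pairs one `sv_pairs` table per library (a single table is treated
#'   as one library); see [project_alignments()] and [read_alignments()].
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param profiles optional list of [library_profile()]s; estimated from the
#'   data when NULL.
#' @param sv_types signature classes to analyse (default all).
#' @param map_qual minimum mapping quality for a uniquely mapping pair.
#' @param mad_cutoff discordance cutoff in insert-size standard deviations.
#' @param min_pairs minimum supporting pairs per paired-end call.
#' @param min_split minimum supporting split reads for a precise call.
#' @param max_candidates split-read candidate cap per call.
#' @param include_softclips admit soft-clipped reads as split candidates.
#' @param merge_z translocation merge window in bp.
#' @param sample_size pairs sampled for library profiling.
#' @param ... further arguments to [refine_call()].
#' @return an object of class `svdelver_calls`: `calls` (final merged call
#'   table), `pe_calls` (imprecise paired-end calls before refinement),
#'   `profiles`, and the discordant-pair count.
#' @export
sv_call <- function(pairs, genome, profiles = NULL,
                    sv_types = c("DEL", "DUP", "INV", "TRA"),
                    map_qual = 1L, mad_cutoff = 3, min_pairs = 2L,
                    min_split = 2L, max_candidates = 1000L,
                    include_softclips = FALSE, merge_z = 300,
                    sample_size = 10000L, ...) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  if (is.null(profiles)) {
    profiles <- lapply(pairs, estimate_library_profile,
                       sample_size = sample_size, cutoff_sd = mad_cutoff)
  } else if (inherits(profiles, "library_profile")) {
    profiles <- list(profiles)
  }
  disc <- extract_discordant(pairs, profiles, map_qual = map_qual)
  want <- sub("_.*$", "", disc$signature) %in% sv_types
  disc <- disc[want, , drop = FALSE]
  class(disc) <- c("sv_discordant", "data.frame")
  pe <- call_paired_end(disc, min_pairs = min_pairs)
  cand <- collect_split_candidates(pe, pairs, profiles, L = max_candidates,
                                   include_softclips = include_softclips)
  refined <- refine_calls(pe, cand, genome, min_split = min_split, ...)
  merge_all <- function(calls) {
    if (is.null(calls$sr_support)) {
      calls$sr_support <- NA_integer_; calls$srq <- NA_real_
      calls$inslen <- NA_integer_; calls$ins_seq <- NA_character_
      calls$homlen <- NA_integer_; calls$consensus <- NA_character_
      calls$sv_length <- ifelse(calls$sv_type == "TRA", NA_real_, calls$end - calls$start)
    }
    calls$pos2_b <- NA_real_
    calls$support_left <- NA_integer_
    calls$support_right <- NA_integer_
    calls$merged_from <- vector("list", nrow(calls))
    calls <- merge_inversions(calls)
    calls <- merge_translocations(calls, z = merge_z)
    finalize_calls(calls)
  }
  merged <- merge_all(refined)
  pe_merged <- merge_all(pe)
  structure(list(calls = merged, pe_calls = pe_merged, profiles = profiles,
                 n_discordant = nrow(disc)),
            class = "svdelver_calls")
}

#' @export
print.svdelver_calls <- function(x, ...) {
  cat(sprintf("svdelver calls: %d final (%d precise), %d paired-end clusters, %d discordant pairs\n",
              nrow(x$calls), sum(x$calls$precise), nrow(x$pe_calls), x$n_discordant))
  if (nrow(x$calls)) print(table(x$calls$sv_type, ifelse(x$calls$precise, "precise", "imprecise")))
  invisible(x)
}

#' @export
summary.svdelver_calls <- function(object, ...) {
  calls <- object$calls
  if (!nrow(calls)) { cat("no calls\n"); return(invisible(object)) }
  cols <- c("id", "sv_type", "chrom", "start", "end", "chrom2", "pos2",
            "pe_support", "sr_support", "mapq_mean", "precise", "filter")
  print(calls[, intersect(cols, names(calls))], row.names = FALSE)
  invisible(object)
}
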