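#' @useDynLib svdelver, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad rnorm runif rbinom
#' @importFrom utils head write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around Biostrings for plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Fetch [start, end) (0-based half-open) from a named character genome.
## strand "-" returns the reverse complement.
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("unknown contig: ", chrom)
  n <- nchar(seq)
  if (start < 0L || end > n || start > end)
    stop(sprintf("fetch [%d,%d) out of bounds for %s (length %d)", start, end, chrom, n))
  s <- substr(seq, start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file path.
#' @return named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a named character genome to FASTA (with .fai index)
#' @param genome named character vector of contig sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
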