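## Minimal finalised-call-shaped row for merge tests.
inv_call <- function(id, side, start, end, precise = FALSE, sr = NA_integer_) {
  data.frame(call_id = id, sv_type = "INV", side = side, chrom = "chrA",
             start = start, end = end, chrom2 = NA_character_, pos2 = NA_real_,
             pe_support = 4L, mapq_mean = 60, precise = precise,
             insert_max = 390, sd_insert = 30,
             sr_support = sr, consensus = NA_character_, srq = NA_real_,
             inslen = NA_integer_, ins_seq = NA_character_, homlen = NA_integer_,
             sv_length = end - start, pos2_b = NA_real_,
             support_left = NA_integer_, support_right = NA_integer_,
             members = I(list(id)), merged_from = I(list(NULL)),
             stringsAsFactors = FALSE)
}

tra_call <- function(id, side, pos, pos2, precise = FALSE) {
  out <- inv_call(id, side, pos, pos, precise)
  out$sv_type <- "TRA"; out$chrom2 <- "chrB"; out$pos2 <- pos2
  out$sv_length <- NA_real_
  out
}

test_that("inversion merging applies the reciprocal-overlap and best-first rules", {
  ## 0.963 reciprocal overlap -> merged
  calls <- rbind(inv_call(1, "LEFT", 1000, 5000), inv_call(2, "RIGHT", 1100, 5050))
  m <- merge_inversions(calls)
  expect_equal(nrow(m), 1)
  expect_equal(m$side, "BOTH")
  expect_equal(m$pe_support, 8)
  ## both imprecise -> midpoint coordinates
  expect_equal(m$start, 1050); expect_equal(m$end, 5025)

  ## reciprocal overlap 0.125 -> not merged
  calls2 <- rbind(inv_call(1, "LEFT", 1000, 5000), inv_call(2, "RIGHT", 4000, 9000))
  expect_equal(nrow(merge_inversions(calls2)), 2)

  ## one left call, two eligible right calls: smaller breakpoint distance wins
  calls3 <- rbind(inv_call(1, "LEFT", 1000, 5000),
                  inv_call(2, "RIGHT", 1040, 5020), # distance 60
                  inv_call(3, "RIGHT", 1010, 5005)) # distance 15
  m3 <- merge_inversions(calls3)
  expect_equal(nrow(m3), 2)
  merged_row <- m3[m3$side == "BOTH", ]
  expect_setequal(merged_row$merged_from[[1]], c(1, 3))

  ## a precise partner contributes its breakpoints unchanged
  calls4 <- rbind(inv_call(1, "LEFT", 980, 5030, precise = TRUE, sr = 6),
                  inv_call(2, "RIGHT", 1000, 5000))
  m4 <- merge_inversions(calls4)
  expect_equal(nrow(m4), 1)
  expect_equal(m4$start, 980); expect_equal(m4$end, 5030)
  expect_true(m4$precise)

  ## merging is idempotent and never grows the table
  expect_equal(nrow(merge_inversions(m)), nrow(m))
})

test_that("translocation merging pairs complementary classes within z", {
  calls <- rbind(tra_call(1, "TRA_1", 10050, 0), tra_call(2, "TRA_3", 10200, 2000))
  m <- merge_translocations(calls, z = 300)
  expect_equal(nrow(m), 1) # |10050 - 10200| = 150 < 300
  expect_equal(m$pos2_b, 2000)

  ## strict inequality at the window edge
  calls2 <- rbind(tra_call(1, "TRA_1", 10000, 0), tra_call(2, "TRA_3", 10301, 2000))
  expect_equal(nrow(merge_translocations(calls2, z = 300)), 2)

  ## different relative orientation never merges
  calls3 <- rbind(tra_call(1, "TRA_1", 10000, 0), tra_call(2, "TRA_2", 10010, 2000))
  expect_equal(nrow(merge_translocations(calls3, z = 300)), 2)

  ## best-first: the closest pair merges first
  calls4 <- rbind(tra_call(1, "TRA_1", 10000, 0),
                  tra_call(2, "TRA_3", 10250, 2000),
                  tra_call(3, "TRA_3", 10020, 2000))
  m4 <- merge_translocations(calls4, z = 300)
  expect_equal(nrow(m4), 2)
  merged_row <- m4[!vapply(m4$merged_from, is.null, logical(1)), ]
  expect_setequal(merged_row$merged_from[[1]], c(1, 3))
})

test_that("VCF output round-trips through an independent parser", {
  skip_if_not_installed("VariantAnnotation")
  sim <- sv_simulate(genome_length = 3e5, n_sv = c(DEL = 2, TRA = 1),
                     coverage = 15, error_rate = 0, seed = 61)
  pr <- project_alignments(sim)
  res <- sv_call(pr, sim$reference)
  vcf_path <- tempfile(fileext = ".vcf")
  tsv_path <- tempfile(fileext = ".tsv")
  write_calls(res$calls, vcf_path, genome = sim$reference, tsv = tsv_path)

  vcf <- VariantAnnotation::readVcf(vcf_path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- res$calls[res$calls$sv_type != "TRA", ]
  for (k in seq_len(nrow(keep))) {
    row <- match(keep$id[k], names(rr))
    expect_false(is.na(row))
    expect_equal(GenomicRanges::start(rr)[row], keep$start[k] + 1) # 1-based POS
    expect_equal(info$END[row], keep$end[k])
    expect_equal(info$PE[row], keep$pe_support[k])
    if (!is.na(keep$sr_support[k]) && keep$sr_support[k] > 0)
      expect_equal(info$SR[row], keep$sr_support[k])
    if (keep$precise[k]) expect_true(info$PRECISE[row])
  }
  ## translocations appear as a breakend pair with reciprocal MATEIDs
  tra_id <- res$calls$id[res$calls$sv_type == "TRA"][1]
  bnd <- grep(paste0("^", tra_id, "_"), names(rr))
  expect_equal(length(bnd), 2)
  expect_setequal(unlist(info$MATEID[bnd]), names(rr)[bnd])

  ## the TSV mirror reproduces the call table
  flat <- read.table(tsv_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(flat), nrow(res$calls))
  expect_equal(flat$start, res$calls$start)
  expect_equal(flat$sr_support, res$calls$sr_support)
  unlink(c(vcf_path, tsv_path))
})

test_that("microinsertions survive refinement and are reported in the VCF", {
  set.seed(62)
  genome <- c(chrA = random_dna(20000))
  call <- data.frame(call_id = 1L, sv_type = "DEL", side = NA_character_,
                     chrom = "chrA", start = 6000, end = 8000,
                     chrom2 = NA_character_, pos2 = NA_real_, pe_support = 4L,
                     mapq_mean = 60, precise = FALSE, insert_max = 390,
                     sd_insert = 30, members = I(list(1:4)),
                     stringsAsFactors = FALSE)
  ins <- mismatch_ins(genome[["chrA"]], 6000, 8001, 8)
  jr <- vapply(1:4, function(i) {
    off <- 15 + 6 * i
    paste0(substr(genome[["chrA"]], 6000 - off + 1, 6000), ins,
           substr(genome[["chrA"]], 8001, 8001 + (66 - off)))
  }, character(1))
  cand <- data.frame(call_id = 1L, seq = jr, anchor_pos = 6000L,
                     read_id = seq_along(jr), stringsAsFactors = FALSE)
  out <- refine_call(call, cand, genome)
  expect_true(out$precise)
  expect_equal(out$inslen, 8L)
  expect_equal(out$ins_seq, ins)

  out$pos2_b <- NA_real_; out$support_left <- NA_integer_
  out$support_right <- NA_integer_; out$merged_from <- list(NULL)
  out <- svdelver:::finalize_calls(out)
  vcf_path <- tempfile(fileext = ".vcf")
  write_calls(out, vcf_path, genome = genome)
  txt <- readLines(vcf_path)
  rec <- txt[!startsWith(txt, "#")]
  expect_match(rec, "INSLEN=8", all = FALSE)
  expect_match(rec, paste0("INSSEQ=", ins), all = FALSE)
  unlink(vcf_path)
})
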