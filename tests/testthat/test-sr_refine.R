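## Deletion-call row in pe_calls shape for refinement tests.
make_call <- function(sv_type = "DEL", chrom = "chrA", start, end,
                      side = NA_character_, chrom2 = NA_character_,
                      pos2 = NA_real_, insert_max = 390) {
  data.frame(call_id = 1L, sv_type = sv_type, side = side, chrom = chrom,
             start = start, end = end, chrom2 = chrom2, pos2 = pos2,
             pe_support = 3L, mapq_mean = 60, precise = FALSE,
             insert_max = insert_max, sd_insert = 30,
             members = I(list(1:3)), stringsAsFactors = FALSE)
}

test_that("SV reference construction back-translates in every geometry", {
  set.seed(51)
  genome <- c(chrA = random_dna(20000), chrB = random_dna(8000))
  calls <- list(
    make_call("DEL", start = 5000, end = 7000),
    make_call("DUP", start = 5000, end = 7000),
    make_call("INV", start = 5000, end = 7000, side = "LEFT"),
    make_call("INV", start = 5000, end = 7000, side = "RIGHT"),
    make_call("TRA", start = 5000, end = 5000, side = "TRA_1",
              chrom2 = "chrB", pos2 = 3000),
    make_call("TRA", start = 5000, end = 5000, side = "TRA_3",
              chrom2 = "chrB", pos2 = 3000))
  for (call in calls) {
    sv_ref <- build_sv_reference(genome, call)
    sm <- sv_ref$segments
    expect_equal(nchar(sv_ref$seq), sum(sm$sv_end - sm$sv_start))
    ## segment content round-trips against the genome
    for (k in seq_len(nrow(sm))) {
      piece <- substr(sv_ref$seq, sm$sv_start[k] + 1, sm$sv_end[k])
      expect_identical(piece, svdelver:::genome_fetch(
        genome, sm$chrom[k], sm$g_start[k], sm$g_end[k], sm$strand[k]))
    }
    ## back-translation of sampled junction coordinates is exact
    for (k in seq_len(nrow(sm))) {
      idx <- sample(seq(sm$sv_start[k] + 1, sm$sv_end[k]), 25)
      for (i in idx) {
        bp <- svdelver:::translate_breakpoint(sv_ref, i, "end")
        expect_equal(bp$chrom, sm$chrom[k])
        if (sm$strand[k] == "+") {
          expect_equal(bp$pos, sm$g_start[k] + (i - sm$sv_start[k]))
        } else {
          expect_equal(bp$pos, sm$g_end[k] - (i - sm$sv_start[k]))
        }
      }
    }
  }
  ## deletion geometry is a plain extraction of the padded call interval
  del_ref <- build_sv_reference(genome, calls[[1]])
  expect_identical(del_ref$seq, substr(genome[["chrA"]], 5000 - 390 + 1, 7000 + 390))
})

test_that("inversion junction reads become deletion-type splits on the SV reference", {
  set.seed(52)
  genome <- c(chrA = random_dna(20000))
  S <- 8000L; E <- 9000L # 1 kb inversion
  prefix <- substr(genome[["chrA"]], S - 40 + 1, S)
  suffix <- revcomp(substr(genome[["chrA"]], E - 35 + 1, E))
  junction_read <- paste0(prefix, suffix)
  call <- make_call("INV", start = S, end = E, side = "LEFT")
  sv_ref <- build_sv_reference(genome, call)
  ## both sides occur exactly once, in prefix-before-suffix order:
  ## the rearranged reference turns the inversion junction into a plain split
  p_at <- regexpr(prefix, sv_ref$seq, fixed = TRUE)
  s_at <- regexpr(suffix, sv_ref$seq, fixed = TRUE)
  expect_gt(p_at, 0); expect_gt(s_at, 0)
  expect_gt(s_at, p_at)
  ## and the diagonal machinery sees exactly two dominant diagonals
  dp <- diagonal_hits(junction_read, svdelver:::kmer_index(sv_ref$seq, 7), 7)
  expect_gte(sum(dp$count >= 3), 2)
  sel <- select_read_offset(dp, 3)
  expect_false(is.null(sel))
  ## the junction does not align contiguously anywhere in the plain reference
  expect_false(grepl(junction_read, genome[["chrA"]], fixed = TRUE))
  expect_false(grepl(junction_read, revcomp(genome[["chrA"]]), fixed = TRUE))
  ## a full refinement on constructed junction reads recovers [S, E) exactly
  jr <- vapply(c(15, 25, 35, 45), function(off)
    paste0(substr(genome[["chrA"]], S - off + 1, S),
           revcomp(substr(genome[["chrA"]], E - (75 - off) + 1, E))), character(1))
  cand <- data.frame(call_id = 1L, seq = jr, anchor_pos = S,
                     read_id = seq_along(jr), stringsAsFactors = FALSE)
  out <- refine_call(make_call("INV", start = S - 60, end = E + 45, side = "LEFT"),
                     cand, genome)
  expect_true(out$precise)
  expect_lte(abs(out$start - S), out$homlen)
  expect_equal(out$end - out$start, E - S)
})

test_that("diagonal k-mer counting matches the worked hit arithmetic", {
  set.seed(53)
  ref <- random_dna(400)
  idx <- svdelver:::kmer_index(ref, 7)

  ## exact 36-mer at offset 10: one diagonal with L - k + 1 = 30 hits
  read <- substr(ref, 11, 46)
  dp <- diagonal_hits(read, idx, 7)
  expect_equal(dp$diag, 10)
  expect_equal(dp$count, 30)

  ## one substitution destroys at most k hits on the diagonal
  mut <- read
  substr(mut, 18, 18) <- setdiff(c("A", "C", "G", "T"), substr(read, 18, 18))[1]
  dpm <- diagonal_hits(mut, idx, 7)
  expect_gte(dpm$count[dpm$diag == 10], 30 - 7)

  ## read across a 65 bp deletion-type junction: two dominant diagonals 65 apart
  junction_read <- paste0(substr(ref, 101, 136), substr(ref, 202, 240))
  dpj <- diagonal_hits(junction_read, idx, 7)
  top2 <- dpj$diag[order(-dpj$count)][1:2]
  expect_equal(abs(diff(sort(top2))), 65)
  sel <- select_read_offset(dpj, 3)
  expect_equal(sel$offset, 65)

  ## total counted hits never exceed the read's k-mer count
  expect_lte(sum(dpj$count), dpj$n_kmers)
})

test_that("offset selection applies the k_min, survivor and coverage filters", {
  prof <- structure(list(diag = c(7L, 72L), count = c(7L, 16L),
                         mean_offset = c(2, 10), n_kmers = 30L),
                    class = "diagonal_profile")
  sel <- select_read_offset(prof, 3)
  expect_equal(sel$offset, 65)
  expect_equal(sel$prefix_diag, 7)

  ## a single surviving diagonal rejects the read (concordant read)
  one <- structure(list(diag = 5L, count = 20L, mean_offset = 3, n_kmers = 30L),
                   class = "diagonal_profile")
  expect_null(select_read_offset(one, 3))

  ## three diagonals: the most-supported consecutive pair wins
  three <- structure(list(diag = c(3L, 68L, 200L), count = c(11L, 12L, 3L),
                          mean_offset = c(2, 20, 25), n_kmers = 30L),
                     class = "diagonal_profile")
  expect_equal(select_read_offset(three, 3)$offset, 65)

  ## top-2 coverage below half the k-mers rejects
  weak <- structure(list(diag = c(3L, 68L), count = c(5L, 6L),
                         mean_offset = c(2, 20), n_kmers = 30L),
                    class = "diagonal_profile")
  expect_null(select_read_offset(weak, 3))
})

test_that("offset voting is modal with deterministic tie-breaks", {
  v <- vote_offset(c(65, 65, 65), 2)
  expect_equal(v$offset, 65)
  expect_equal(length(v$support), 3)

  expect_null(vote_offset(c(65, 120), 2)) # no majority of two

  v2 <- vote_offset(c(65, 65, 65, 65, 66, 66), 2)
  expect_equal(v2$offset, 65)

  ## tie broken toward the paired-end predicted size
  v3 <- vote_offset(c(65, 65, 66, 66), 2, pe_size = 66)
  expect_equal(v3$offset, 66)
  ## and then toward the smaller offset
  v4 <- vote_offset(c(65, 65, 66, 66), 2, pe_size = NA)
  expect_equal(v4$offset, 65)
})

test_that("consensus is a per-column majority with read-order tie-break", {
  expect_equal(consensus_sequence(rep("ACGTACGT", 3), rep(10, 3))$seq, "ACGTACGT")

  cs <- consensus_sequence(c("AAAA", "AAAA", "ACAA"), c(0, 0, 0))
  expect_equal(cs$seq, "AAAA") # column {A, A, C} -> A

  tie <- consensus_sequence(c("AT", "CT"), c(5, 5))
  expect_equal(tie$seq, "AT") # tie {A, C} -> earliest read

  ## non-overlapping placements fail the call
  expect_null(consensus_sequence(c("AAAA", "TTTT"), c(0, 100)))
})

test_that("split alignment recovers clean, inserted and homologous junctions", {
  set.seed(54)
  A <- random_dna(300); B <- random_dna(300)
  ref <- paste0(A, B)

  ## clean junction: consensus = suffix(A) + prefix(B) skipping 150 bp
  cons <- paste0(substr(A, 261, 300), substr(B, 151, 190))
  sp <- split_alignment(cons, ref)
  expect_equal(sp$i, 40); expect_equal(sp$j, 41)
  expect_equal(sp$ref_prefix_end, 300)
  expect_equal(sp$ref_suffix_start, 450)
  expect_equal(sp$microinsertion, "")
  expect_equal(sp$score, 5 * nchar(cons))
  expect_equal(sp$quality, 1)

  ## non-template microinsertion at the junction, constructed to mismatch
  ## both landing sites; the unaligned-gap split must win over absorbing it
  ins <- mismatch_ins(ref, 300, 471, 10)
  cons2 <- paste0(substr(A, 261, 300), ins, substr(ref, 471, 510))
  sp2 <- split_alignment(cons2, ref)
  expect_equal(sp2$j - sp2$i - 1L, 10L)
  expect_equal(sp2$microinsertion, ins)
  ## and the exhaustive oracle agrees on the score
  expect_equal(sp2$score, split_oracle(cons2, ref)$score)

  ## microhomology: H present on both junction sides, breakpoint left-aligned;
  ## guard bases around H stop the tract from extending by accident
  H <- "ACGTACGT"
  mid <- random_dna(200)
  substr(A, 300, 300) <- "A"; substr(mid, 1, 1) <- "C"
  substr(mid, 200, 200) <- "G"; B2 <- B; substr(B2, 1, 1) <- "T"
  refh <- paste0(A, H, mid, H, B2)
  consh <- paste0(substr(A, 271, 300), H, substr(B2, 1, 30))
  sph <- split_alignment(consh, refh)
  expect_equal(sph$homlen, nchar(H))
  expect_equal(sph$ref_prefix_end, 300) # left-aligned: junction before H
})

test_that("split alignment equals the exhaustive split-enumeration oracle", {
  set.seed(55)
  agree <- 0L; n_cases <- 60L
  for (rep in seq_len(n_cases)) {
    ref <- random_dna(300)
    i0 <- sample(40:80, 1); j0 <- sample(150:250, 1)
    len1 <- sample(20:40, 1); len2 <- sample(20:40, 1)
    cons <- paste0(substr(ref, i0 - len1 + 1, i0), substr(ref, j0, j0 + len2 - 1))
    ## sprinkle up to two substitution errors
    for (e in seq_len(sample(0:2, 1))) {
      p <- sample(nchar(cons), 1)
      substr(cons, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- split_alignment(cons, ref)
    want <- split_oracle(cons, ref)
    if (!is.null(got) && isTRUE(all.equal(got$score, want$score))) agree <- agree + 1L
  }
  expect_gte(agree / n_cases, 0.99)
})

test_that("candidate collection windows follow the anchored-mate rule", {
  sim <- sv_simulate(genome_length = 3e5, n_sv = c(DEL = 2),
                     size_range = c(2000, 2000), coverage = 15,
                     error_rate = 0, seed = 56)
  pr <- project_alignments(sim)
  prof <- estimate_library_profile(pr)
  disc <- extract_discordant(pr, prof)
  pe <- call_paired_end(disc)
  cand <- collect_split_candidates(pe, pr, prof)
  expect_gt(nrow(cand), 0)
  ## every candidate's anchor is within reach of its call's breakpoints
  reach <- prof$median_insert + 2 * prof$sd_insert
  for (k in seq_len(nrow(cand))) {
    call <- pe[pe$call_id == cand$call_id[k], ]
    d <- min(abs(cand$anchor_pos[k] - call$start), abs(cand$anchor_pos[k] - call$end))
    expect_lte(d, reach)
  }
  ## the candidate cap truncates each call's set
  cand2 <- collect_split_candidates(pe, pr, prof, L = 2L)
  expect_true(all(table(cand2$call_id) <= 2))
})

test_that("refinement hits exact breakpoints and degrades gracefully", {
  sim <- sv_simulate(genome_length = 4e5, n_sv = c(DEL = 3), coverage = 15,
                     error_rate = 0, seed = 57)
  pr <- project_alignments(sim)
  res <- sv_call(pr, sim$reference)
  prec <- res$calls[res$calls$precise & res$calls$sv_type == "DEL", ]
  expect_equal(nrow(prec), 3)
  for (k in seq_len(nrow(prec))) {
    tr <- sim$truth[which.min(abs(sim$truth$start - prec$start[k])), ]
    hl <- prec$homlen[k]
    ## exact up to a shift within the junction's microhomology tract
    expect_lte(abs(prec$start[k] - tr$start), hl)
    expect_equal(prec$end[k] - prec$start[k], tr$size)
  }

  ## split-read length inconsistent with the paired-end length is rejected
  genome <- c(chrA = random_dna(20000))
  call <- make_call("DEL", start = 6000, end = 8000) # PE length 2000
  ## candidates from a 1.5 kb deletion junction at the same locus
  jr <- vapply(1:4, function(i) {
    off <- 10 + 7 * i
    paste0(substr(genome[["chrA"]], 6000 - off + 1, 6000),
           substr(genome[["chrA"]], 7501, 7501 + (74 - off)))
  }, character(1))
  cand <- data.frame(call_id = 1L, seq = jr, anchor_pos = 6000L,
                     read_id = seq_along(jr), stringsAsFactors = FALSE)
  out <- refine_call(call, cand, genome)
  expect_false(out$precise) # 1500 vs 2000 is a 25% disagreement > 10%

  ## zero candidates leave the call imprecise and untouched
  out0 <- refine_call(call, cand[0, ], genome)
  expect_false(out0$precise)
  expect_equal(out0$start, 6000); expect_equal(out0$end, 8000)
})
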