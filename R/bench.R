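#' Match SV calls against a simulation truth table
#'
#' Greedy one-to-one matching of same-type call/truth pairs. Intrachromosomal
#' calls match by descending reciprocal overlap (at least `ro`, default 0.8).
#' Translocations match when the insertion-chromosome breakpoint and the
#' partner-chromosome breakpoint are each within `tra_tol` bp of the truth
#' (both partner breakpoints). Each truth event and each call is used at most
#' once: a second call on a matched truth event counts as a false positive.
#'
#' @param calls call table (rows of one caller mode), columns `sv_type`,
#'   `chrom`, `start`, `end`, and `chrom2`/`pos2` (+ optional `pos2_b`) for
#'   translocations.
#' @param truth truth table from [sv_simulate()].
#' @param ro reciprocal overlap threshold for intrachromosomal events.
#' @param tra_tol breakpoint tolerance for translocations (bp), typically the
#'   library insert cutoff.
#' @return list with `tp`, `fp`, `fn` counts, per-type breakdown, and the
#'   matched truth ids.
#' @export
match_calls <- function(calls, truth, ro = 0.8, tra_tol = 390) {
  types <- unique(truth$sv_type)
  tp <- fp <- fn <- 0L
  matched_ids <- character(0)
  per_type <- list()
  for (ty in types) {
    tr <- truth[truth$sv_type == ty, , drop = FALSE]
    cl <- calls[calls$sv_type == ty, , drop = FALSE]
    n_t <- nrow(tr); n_c <- nrow(cl)
    if (n_c == 0L) {
      tp_t <- 0L; fp_t <- 0L
    } else if (ty != "TRA") {
      grid <- expand.grid(c = seq_len(n_c), t = seq_len(n_t))
      grid <- grid[cl$chrom[grid$c] == tr$chrom[grid$t], , drop = FALSE]
      grid$ro <- reciprocal_overlap(cl$start[grid$c], cl$end[grid$c],
                                    tr$start[grid$t], tr$end[grid$t])
      grid <- grid[grid$ro >= ro, , drop = FALSE]
      grid <- grid[order(-grid$ro, grid$c, grid$t), , drop = FALSE]
      used_c <- logical(n_c); used_t <- logical(n_t)
      for (k in seq_len(nrow(grid))) {
        ci <- grid$c[k]; ti <- grid$t[k]
        if (used_c[ci] || used_t[ti]) next
        used_c[ci] <- TRUE; used_t[ti] <- TRUE
        matched_ids <- c(matched_ids, tr$id[ti])
      }
      tp_t <- sum(used_t); fp_t <- n_c - sum(used_c)
    } else {
      ## translocations: both partner breakpoints within tolerance
      used_c <- logical(n_c); used_t <- logical(n_t)
      grid <- expand.grid(c = seq_len(n_c), t = seq_len(n_t))
      grid <- grid[cl$chrom[grid$c] == tr$chrom[grid$t] &
                   cl$chrom2[grid$c] == tr$chrom2[grid$t], , drop = FALSE]
      if (nrow(grid)) {
        d_ins <- abs(cl$start[grid$c] - tr$start[grid$t])
        seg_bp <- function(p, ti) pmin(abs(p - tr$pos2_start[ti]), abs(p - tr$pos2_end[ti]))
        d_seg <- seg_bp(cl$pos2[grid$c], grid$t)
        if ("pos2_b" %in% names(cl)) {
          p2b <- cl$pos2_b[grid$c]
          d2b <- ifelse(is.na(p2b), Inf, seg_bp(p2b, grid$t))
          d_seg <- pmin(d_seg, d2b, na.rm = TRUE)
        }
        grid$d <- d_ins + d_seg
        grid <- grid[d_ins <= tra_tol & d_seg <= tra_tol, , drop = FALSE]
        grid <- grid[order(grid$d, grid$c, grid$t), , drop = FALSE]
        for (k in seq_len(nrow(grid))) {
          ci <- grid$c[k]; ti <- grid$t[k]
          if (used_c[ci] || used_t[ti]) next
          used_c[ci] <- TRUE; used_t[ti] <- TRUE
          matched_ids <- c(matched_ids, tr$id[ti])
        }
      }
      tp_t <- sum(used_t); fp_t <- n_c - sum(used_c)
    }
    fn_t <- n_t - tp_t
    per_type[[ty]] <- c(tp = tp_t, fp = fp_t, fn = fn_t)
    tp <- tp + tp_t; fp <- fp + fp_t; fn <- fn + fn_t
  }
  list(tp = tp, fp = fp, fn = fn, per_type = per_type, matched = matched_ids)
}

## Sensitivity / PPV with the 0/0 guard.
safe_rate <- function(num, den) if (den == 0L) NA_real_ else num / den

#' Run the simulation benchmark over a parameter grid
#'
#' For each grid cell and replicate: simulate a genome with planted events,
#' project the reads to truth alignments, run the caller, and score the
#' paired-end (PE) and split-read-refined (SR) call sets against the truth.
#' Replicate r of every cell uses seed `seed + r - 1`, so the default
#' five-replicate run uses seeds 1..5 when `seed = 1`.
#'
#' @param cells data.frame of grid cells with any of the columns `coverage`,
#'   `read_len`, `insert_mean`, `insert_sd`, `error_rate`, `sv_type`,
#'   `n_events`, `genome_length` (missing columns take the defaults below).
#' @param replicates simulations per cell (default 5; the median is reported).
#' @param seed base seed.
#' @param genome_length,n_events,size_range defaults for cells that do not
#'   override them.
#' @param ro reciprocal overlap matching threshold.
#' @return list with `replicates` (one row per cell/replicate/mode) and
#'   `summary` (median sensitivity and PPV per cell and mode).
#' @export
run_benchmark <- function(cells, replicates = 5L, seed = 1L,
                          genome_length = 5e6, n_events = 50L,
                          size_range = c(500, 5000), ro = 0.8) {
  val <- function(x, d) if (is.null(x) || (length(x) == 1L && is.na(x))) d else x
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- as.list(cells[ci, , drop = FALSE])
    cov <- val(cell$coverage, 15)
    rl <- val(cell$read_len, 75L)
    imu <- val(cell$insert_mean, 300)
    isd <- val(cell$insert_sd, 30)
    er <- val(cell$error_rate, 0.01)
    ty <- val(cell$sv_type, "DEL")
    ne <- val(cell$n_events, n_events)
    gl <- val(cell$genome_length, genome_length)
    for (rep_i in seq_len(replicates)) {
      s <- seed + rep_i - 1L
      n_sv <- stats::setNames(ne, ty)
      sim <- sv_simulate(genome_length = gl, n_sv = n_sv, size_range = size_range,
                         coverage = cov, read_len = rl, insert_mean = imu,
                         insert_sd = isd, error_rate = er, seed = s)
      pairs <- project_alignments(sim)
      res <- sv_call(pairs, sim$reference)
      tol <- res$profiles[[1]]$insert_max
      pe <- match_calls(res$pe_calls[res$pe_calls$sv_type == ty, , drop = FALSE],
                        sim$truth, ro = ro, tra_tol = tol)
      sr_set <- res$calls[res$calls$sv_type == ty & res$calls$precise, , drop = FALSE]
      sr <- match_calls(sr_set, sim$truth, ro = ro, tra_tol = tol)
      for (mode in c("PE", "SR")) {
        m <- if (mode == "PE") pe else sr
        rows[[length(rows) + 1L]] <- data.frame(
          cell = ci, coverage = cov, read_len = rl, insert_mean = imu,
          insert_sd = isd, error_rate = er, sv_type = ty, replicate = rep_i,
          seed = s, mode = mode, tp = m$tp, fp = m$fp, fn = m$fn,
          sensitivity = safe_rate(m$tp, m$tp + m$fn),
          ppv = safe_rate(m$tp, m$tp + m$fp),
          stringsAsFactors = FALSE)
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(sensitivity, ppv) ~ cell + sv_type + mode +
                            coverage + read_len + insert_mean + insert_sd,
                          data = reps, FUN = median)
  list(replicates = reps, summary = agg[order(agg$cell, agg$mode), ])
}
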