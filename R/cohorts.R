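# Rank field indices by reported yield, descending; ties broken
# lexicographically by field_id for reproducibility.
rank_by_yield <- function(table, idx) {
  idx[order(-table$yield_t_ha[idx], table$field_id[idx])]
}

new_cohort <- function(table, subset, cohort, idx, params, log_lines) {
  structure(list(
    spec = c(list(subset = subset, cohort = cohort), params),
    member_ids = table$field_id[idx],
    yields = table$yield_t_ha[idx],
    sprayed = table$foliar_fungicide[idx] == 1,
    selection_log = log_lines
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort %s%s: %d fields, yields %.2f-%.2f t/ha\n",
              x$spec$subset, x$spec$cohort, length(x$member_ids),
              if (length(x$yields)) min(x$yields) else NA,
              if (length(x$yields)) max(x$yields) else NA))
  invisible(x)
}

#' Per-TED highest-yielding cohorts (subset s1)
#'
#' Within each of the `k_teds` most-populous TEDs, selects the `top_n`
#' highest-yielding sprayed fields (cohort c1) and the `top_n`
#' highest-yielding unsprayed fields (cohort c2), ranked by reported yield.
#' TEDs with fewer than `top_n` eligible fields contribute all they have; the
#' shortfall is noted in the selection log.
#'
#' @param table A `field_table`.
#' @param k_teds Number of most-populous TEDs.
#' @param top_n Target cohort size per TED.
#' @return Named list of `cohort` objects, keys like `"s1c1:T001"`.
#' @export
cohort_s1 <- function(table, k_teds = 12, top_n = 20) {
  stopifnot(k_teds >= 1, top_n >= 1)
  out <- list()
  for (ted in top_teds(table, k_teds)) {
    for (ci in 1:2) {
      want_spray <- if (ci == 1) 1L else 0L
      pool <- which(table$ted_id == ted & table$foliar_fungicide == want_spray)
      ranked <- rank_by_yield(table, pool)
      take <- utils::head(ranked, top_n)
      log <- sprintf("s1c%d TED %s: %d eligible, took %d%s", ci, ted,
                     length(pool), length(take),
                     if (length(take) < top_n)
                       sprintf(" (shortfall of %d)", top_n - length(take))
                     else "")
      out[[sprintf("s1c%d:%s", ci, ted)]] <-
        new_cohort(table, "s1", sprintf("c%d", ci), take,
                   list(ted_id = ted, top_n = top_n), log)
    }
  }
  out
}

#' Global extreme-yield cohorts (subset s2)
#'
#' Across the whole table: the `n` highest-yielding sprayed fields (c1), the
#' `n` lowest-yielding sprayed fields (c2), the `n` highest-yielding
#' unsprayed fields (c3), and the `n` lowest-yielding unsprayed fields (c4).
#'
#' @param table A `field_table`.
#' @param n Cohort size (truncated with a log entry if a stratum is smaller).
#' @return Named list of four `cohort` objects (`s2c1`..`s2c4`).
#' @export
cohort_s2 <- function(table, n = 100) {
  specs <- list(c1 = c(1L, +1), c2 = c(1L, -1), c3 = c(0L, +1), c4 = c(0L, -1))
  out <- list()
  for (nm in names(specs)) {
    spray <- specs[[nm]][1]
    highest <- specs[[nm]][2] > 0
    pool <- which(table$foliar_fungicide == spray)
    ranked <- rank_by_yield(table, pool)
    if (!highest) ranked <- rev(ranked)
    take <- utils::head(ranked, n)
    log <- sprintf("s2%s: %d eligible, took %d (%s-yielding, %s)", nm,
                   length(pool), length(take),
                   if (highest) "highest" else "lowest",
                   if (spray == 1) "sprayed" else "unsprayed")
    out[[paste0("s2", nm)]] <- new_cohort(table, "s2", nm, take,
                                          list(n = n, sprayed = spray == 1,
                                               highest = highest), log)
  }
  out
}

#' Top-percentile yield cohorts by spray status (subset s3)
#'
#' The fields at or above the given yield percentile, computed separately
#' within the sprayed stratum (c1) and the unsprayed stratum (c2).
#'
#' @param table A `field_table`.
#' @param percentile Percentile threshold in (0, 100); 90 selects each
#'   stratum's top decile.
#' @return Named list of two `cohort` objects (`s3c1`, `s3c2`).
#' @export
cohort_s3 <- function(table, percentile = 90) {
  stopifnot(percentile >= 0, percentile < 100)
  out <- list()
  for (ci in 1:2) {
    spray <- if (ci == 1) 1L else 0L
    pool <- which(table$foliar_fungicide == spray)
    if (length(pool) == 0) stop("empty stratum for s3", call. = FALSE)
    thr <- stats::quantile(table$yield_t_ha[pool], percentile / 100,
                           names = FALSE)
    take <- rank_by_yield(table, pool[table$yield_t_ha[pool] >= thr])
    log <- sprintf("s3c%d: threshold %.3f t/ha (P%g of %d %s fields), took %d",
                   ci, thr, percentile, length(pool),
                   if (spray == 1) "sprayed" else "unsprayed", length(take))
    out[[sprintf("s3c%d", ci)]] <- new_cohort(table, "s3", sprintf("c%d", ci),
                                              take,
                                              list(percentile = percentile,
                                                   threshold = thr), log)
  }
  out
}

#' Fungicide-only versus co-application cohorts (subset s4)
#'
#' Cohort c1 holds every field sprayed with foliar fungicide but not foliar
#' insecticide. Cohort c2 is a seeded uniform sample, without replacement, of
#' fields sprayed with both, restricted to yields within the range of c1's
#' yields and sized to match c1 (or fewer, logged).
#'
#' @param table A `field_table`.
#' @param seed Integer seed for the c2 sample.
#' @return Named list of two `cohort` objects (`s4c1`, `s4c2`).
#' @export
cohort_s4 <- function(table, seed = 1) {
  c1_idx <- which(table$foliar_fungicide == 1 & table$foliar_insecticide == 0)
  both_idx <- which(table$foliar_fungicide == 1 & table$foliar_insecticide == 1)
  if (length(c1_idx) == 0 || length(both_idx) == 0) {
    stop("s4 requires both fungicide-only and co-applied fields", call. = FALSE)
  }
  yr <- range(table$yield_t_ha[c1_idx])
  pool <- both_idx[table$yield_t_ha[both_idx] >= yr[1] &
                     table$yield_t_ha[both_idx] <= yr[2]]
  if (length(pool) == 0) stop("no co-applied fields within the s4c1 yield range",
                              call. = FALSE)
  n2 <- min(length(c1_idx), length(pool))
  set.seed(seed)
  c2_idx <- sort(sample(pool, n2))
  log1 <- sprintf("s4c1: all %d fungicide-only fields, yield range [%.3f, %.3f]",
                  length(c1_idx), yr[1], yr[2])
  log2 <- sprintf("s4c2: sampled %d of %d in-range co-applied fields (seed %d)%s",
                  n2, length(pool), seed,
                  if (n2 < length(c1_idx)) " (short of c1 size)" else "")
  list(
    s4c1 = new_cohort(table, "s4", "c1", rank_by_yield(table, c1_idx),
                      list(), log1),
    s4c2 = new_cohort(table, "s4", "c2", rank_by_yield(table, c2_idx),
                      list(seed = seed, yield_range = yr), log2)
  )
}
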