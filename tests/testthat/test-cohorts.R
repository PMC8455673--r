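co_tbl <- simulate_fields(dgp_config(n_fields = 2738, seed = 29))$fields

test_that("s1 takes the top-n by observed yield per TED, logging shortfalls", {
  cs <- cohort_s1(co_tbl, k_teds = 12, top_n = 20)
  expect_length(cs, 24)
  teds <- top_teds(co_tbl, 12)
  one <- cs[[sprintf("s1c1:%s", teds[1])]]
  # brute-force re-sort oracle
  pool <- co_tbl[co_tbl$ted_id == teds[1] & co_tbl$foliar_fungicide == 1, ]
  expected <- head(pool$field_id[order(-pool$yield_t_ha, pool$field_id)], 20)
  expect_identical(one$member_ids, expected)
  expect_true(all(one$sprayed))

  # a TED with fewer eligible fields than top_n takes all and logs it
  thin <- as.data.frame(co_tbl[co_tbl$ted_id == teds[1], ])
  thin_spr <- thin[thin$foliar_fungicide == 1, ][1:5, ]
  thin_unspr <- thin[thin$foliar_fungicide == 0, ]
  tt <- field_table(rbind(thin_spr, thin_unspr))
  cs_thin <- cohort_s1(tt, k_teds = 1, top_n = 20)
  c1 <- cs_thin[[1]]
  expect_length(c1$member_ids, 5)
  expect_match(c1$selection_log, "shortfall")
})

test_that("s2 extreme-yield cohorts respect order statistics", {
  cs <- cohort_s2(co_tbl, n = 100)
  expect_equal(unname(vapply(cs, function(x) length(x$member_ids), integer(1))),
               rep(100L, 4))
  # highest-sprayed min >= lowest-sprayed max when 2n <= sprayed count
  expect_gte(min(cs$s2c1$yields), max(cs$s2c2$yields))
  expect_gte(min(cs$s2c3$yields), max(cs$s2c4$yields))
  expect_true(all(cs$s2c1$sprayed) && all(cs$s2c2$sprayed))
  expect_true(!any(cs$s2c3$sprayed) && !any(cs$s2c4$sprayed))
  # sort oracle
  spr <- co_tbl[co_tbl$foliar_fungicide == 1, ]
  expected <- head(spr$field_id[order(-spr$yield_t_ha, spr$field_id)], 100)
  expect_identical(cs$s2c1$member_ids, expected)
})

test_that("s3 matches a brute-force within-stratum quantile", {
  cs <- cohort_s3(co_tbl, percentile = 90)
  for (ci in 1:2) {
    spray <- if (ci == 1) 1 else 0
    y <- co_tbl$yield_t_ha[co_tbl$foliar_fungicide == spray]
    thr <- quantile(y, 0.9, names = FALSE)
    expect_equal(length(cs[[ci]]$member_ids), sum(y >= thr))
    expect_true(all(cs[[ci]]$yields >= thr))
  }
  # under randomized adoption the sprayed top decile sits above the unsprayed
  # one by roughly the configured treatment effect
  expect_lt(abs((mean(cs$s3c1$yields) - mean(cs$s3c2$yields)) - 0.33), 0.2)

  whole <- cohort_s3(co_tbl, percentile = 0)
  expect_equal(length(whole$s3c1$member_ids),
               sum(co_tbl$foliar_fungicide == 1))

  # tiny stratum: 10 sprayed fields at P90 keeps 1-2 depending on ties
  tiny <- as.data.frame(co_tbl)[c(which(co_tbl$foliar_fungicide == 1)[1:10],
                                  which(co_tbl$foliar_fungicide == 0)[1:10]), ]
  cs_tiny <- cohort_s3(field_table(tiny), percentile = 90)
  expect_true(length(cs_tiny$s3c1$member_ids) %in% 1:2)
})

test_that("s4 matches on yield range, deterministically, with a plausible c1 size", {
  cs <- cohort_s4(co_tbl, seed = 5)
  yr <- range(cs$s4c1$yields)
  expect_true(all(cs$s4c2$yields >= yr[1] & cs$s4c2$yields <= yr[2]))
  expect_lte(length(cs$s4c2$member_ids), length(cs$s4c1$member_ids))
  expect_false(any(duplicated(cs$s4c2$member_ids)))

  again <- cohort_s4(co_tbl, seed = 5)
  expect_identical(cs$s4c2$member_ids, again$s4c2$member_ids)
  other <- cohort_s4(co_tbl, seed = 6)
  expect_false(identical(cs$s4c2$member_ids, other$s4c2$member_ids))

  # binomial expectation: fungicide-only fields are about (1 - 0.748) of sprayed
  n_spr <- sum(co_tbl$foliar_fungicide == 1)
  p <- 1 - 0.748
  expect_lt(abs(length(cs$s4c1$member_ids) - n_spr * p),
            3 * sqrt(n_spr * p * (1 - p)))
})

test_that("every cohort member satisfies its selection predicate post hoc", {
  all_cohorts <- c(cohort_s1(co_tbl), cohort_s2(co_tbl), cohort_s3(co_tbl),
                   cohort_s4(co_tbl, seed = 1))
  for (nm in names(all_cohorts)) {
    ch <- all_cohorts[[nm]]
    idx <- match(ch$member_ids, co_tbl$field_id)
    expect_false(anyNA(idx), label = nm)
    expect_false(any(duplicated(ch$member_ids)), label = nm)
    expect_equal(unname(ch$yields), co_tbl$yield_t_ha[idx], label = nm)
    if (ch$spec$subset %in% c("s1", "s2", "s3")) {
      want <- switch(paste0(ch$spec$subset, ch$spec$cohort),
                     s1c1 = TRUE, s1c2 = FALSE,
                     s2c1 = TRUE, s2c2 = TRUE, s2c3 = FALSE, s2c4 = FALSE,
                     s3c1 = TRUE, s3c2 = FALSE)
      expect_true(all((co_tbl$foliar_fungicide[idx] == 1) == want),
                  label = nm)
    }
  }
})
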