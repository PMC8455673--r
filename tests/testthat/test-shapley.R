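sh_tbl <- small_sim(n = 60, seed = 19)$fields

test_that("a constant model attributes exactly zero everywhere", {
  df <- as.data.frame(sh_tbl)
  df$yield_t_ha <- 3.5
  const_tbl <- field_table(df)
  m <- yield_forest(const_tbl, n_trees = 30, seed = 1)
  att <- mc_shapley(m, const_tbl, const_tbl$field_id[4], n_iter = 50, seed = 2)
  expect_true(all(att$phi == 0))
  expect_equal(attr(att, "efficiency_residual"), 0)
})

test_that("a feature the model ignores gets phi = 0 exactly", {
  f <- function(df) 2 + 0.3 * df$foliar_fungicide +
    0.01 * (df$sowing_doy - 140)
  m <- linear_model(f, c("foliar_fungicide", "sowing_doy", "latitude"),
                    global_mean = mean(f(sh_tbl)))
  att <- mc_shapley(m, sh_tbl, sh_tbl$field_id[3], n_iter = 100, seed = 4)
  expect_equal(att$phi[att$feature == "latitude"], 0)
})

test_that("the MC estimator agrees with exhaustive-subset Shapley on toy models", {
  # 3-feature model with an interaction
  f3 <- function(df) 1 + 0.4 * df$foliar_fungicide +
    0.012 * (df$sowing_doy - 140) +
    0.008 * df$foliar_fungicide * (df$sowing_doy - 140)
  feats3 <- c("foliar_fungicide", "sowing_doy", "latitude")
  m3 <- linear_model(f3, feats3, global_mean = mean(f3(sh_tbl)))
  X3 <- as.data.frame(sh_tbl)[, feats3]
  # 4-feature model adding a soil effect
  f4 <- function(df) f3(df) + 0.1 * (df$soil_ph - 6.5)
  feats4 <- c(feats3, "soil_ph")
  m4 <- linear_model(f4, feats4, global_mean = mean(f4(sh_tbl)))
  X4 <- as.data.frame(sh_tbl)[, feats4]

  for (row_i in c(2, 11)) {
    att <- mc_shapley(m3, sh_tbl, sh_tbl$field_id[row_i], n_iter = 2000,
                      seed = 7)
    for (ft in feats3) {
      exact <- exhaustive_shapley(f3, X3, row_i, ft)
      got <- att[att$feature == ft, ]
      expect_lt(abs(got$phi - exact), 3 * max(got$mc_se, 1e-8))
    }
    att4 <- mc_shapley(m4, sh_tbl, sh_tbl$field_id[row_i], n_iter = 2000,
                       seed = 8)
    for (ft in feats4) {
      exact <- exhaustive_shapley(f4, X4, row_i, ft)
      got <- att4[att4$feature == ft, ]
      expect_lt(abs(got$phi - exact), 3 * max(got$mc_se, 1e-8))
    }
  }
})

test_that("an additive main effect splits by prevalence: delta*(1-p) vs -delta*p", {
  f <- function(df) 3 + 0.4 * df$foliar_fungicide
  feats <- c("foliar_fungicide", "sowing_doy")
  m <- linear_model(f, feats, global_mean = mean(f(sh_tbl)))
  p_hat <- mean(sh_tbl$foliar_fungicide)
  sprayed_id <- sh_tbl$field_id[which(sh_tbl$foliar_fungicide == 1)[1]]
  unsprayed_id <- sh_tbl$field_id[which(sh_tbl$foliar_fungicide == 0)[1]]
  a1 <- mc_shapley(m, sh_tbl, sprayed_id, features = "foliar_fungicide",
                   n_iter = 1500, seed = 3)
  a0 <- mc_shapley(m, sh_tbl, unsprayed_id, features = "foliar_fungicide",
                   n_iter = 1500, seed = 3)
  expect_lt(abs(a1$phi - 0.4 * (1 - p_hat)), 3 * a1$mc_se)
  expect_lt(abs(a0$phi - (-0.4 * p_hat)), 3 * a0$mc_se)
})

test_that("duplicate features receive symmetric attributions", {
  f <- function(df) 2 + 0.05 * (df$soil_ph - 6.5) + 0.05 * (df$ph_twin - 6.5)
  df <- as.data.frame(sh_tbl)
  df$ph_twin <- df$soil_ph
  m <- linear_model(f, c("soil_ph", "ph_twin", "latitude"),
                    global_mean = mean(f(df)))
  tw <- field_table(df)
  att <- mc_shapley(m, tw, tw$field_id[9], n_iter = 2000, seed = 5)
  a <- att[att$feature == "soil_ph", ]
  b <- att[att$feature == "ph_twin", ]
  expect_lt(abs(a$phi - b$phi), 3 * sqrt(a$mc_se^2 + b$mc_se^2))
})

test_that("attributions satisfy efficiency within stochastic tolerance", {
  m <- yield_forest(sh_tbl, n_trees = 100, seed = 2)
  att <- mc_shapley(m, sh_tbl, sh_tbl$field_id[12], n_iter = 800, seed = 6)
  eff <- attr(att, "efficiency_residual")
  expect_lt(abs(eff), 3 * sqrt(sum(att$mc_se^2)) + 1e-8)
  expect_equal(att$prediction[1] - att$global_mean[1] - sum(att$phi), eff)
})

test_that("the Monte-Carlo error shrinks with iterations as 1/sqrt(n)", {
  f <- function(df) 1 + 0.4 * df$foliar_fungicide + 0.01 * df$sowing_doy
  m <- linear_model(f, c("foliar_fungicide", "sowing_doy"),
                    global_mean = mean(f(sh_tbl)))
  id <- sh_tbl$field_id[1]
  est <- function(iters, s) {
    mc_shapley(m, sh_tbl, id, features = "foliar_fungicide",
               n_iter = iters, seed = s)$phi
  }
  v_small <- var(vapply(1:30, function(s) est(100, s), numeric(1)))
  v_large <- var(vapply(1:30, function(s) est(400, s), numeric(1)))
  ratio <- v_small / v_large
  expect_gt(ratio, 2)   # expect about 4
  expect_lt(ratio, 8)
})

test_that("per-field seeding makes results order-independent and reproducible", {
  f <- function(df) 1 + 0.4 * df$foliar_fungicide + 0.01 * df$sowing_doy
  m <- linear_model(f, c("foliar_fungicide", "sowing_doy"),
                    global_mean = mean(f(sh_tbl)))
  ids <- sh_tbl$field_id[1:4]
  fwd <- shapley_fungicide(m, sh_tbl, ids, n_iter = 200, seed = 11)
  rev <- shapley_fungicide(m, sh_tbl, rev(ids), n_iter = 200, seed = 11)
  merged <- merge(fwd[, c("field_id", "phi")], rev[, c("field_id", "phi")],
                  by = "field_id")
  expect_equal(merged$phi.x, merged$phi.y)
})

test_that("phi signs map to the documented agronomic labels", {
  expect_equal(interpret_phi(0.2, sprayed = TRUE), "gain-from-spray")
  expect_equal(interpret_phi(-0.1, sprayed = TRUE), "loss-from-spray")
  expect_equal(interpret_phi(0.05, sprayed = FALSE), "benefit-from-not-spraying")
  expect_equal(interpret_phi(-0.05, sprayed = FALSE), "penalty-for-not-spraying")
  expect_equal(interpret_phi(0, sprayed = TRUE), "no-effect")
  expect_equal(interpret_phi(0, sprayed = FALSE), "no-effect")
})

test_that("unknown fields and features are rejected", {
  m <- yield_forest(sh_tbl, n_trees = 20, seed = 1)
  expect_error(mc_shapley(m, sh_tbl, "NOPE", n_iter = 10), "unknown field")
  expect_error(mc_shapley(m, sh_tbl, sh_tbl$field_id[1],
                          features = "bogus", n_iter = 10), "bogus")
})
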