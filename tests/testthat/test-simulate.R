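test_that("generation is deterministic given the seed", {
  a <- simulate_fields(dgp_config(n_fields = 200, seed = 42))
  b <- simulate_fields(dgp_config(n_fields = 200, seed = 42))
  expect_identical(as.data.frame(a$fields), as.data.frame(b$fields))
  expect_identical(a$truth, b$truth)
  c <- simulate_fields(dgp_config(n_fields = 200, seed = 43))
  expect_false(identical(a$fields$yield_t_ha, c$fields$yield_t_ha))
})

test_that("a degenerate noiseless process returns the baseline yield everywhere", {
  cfg <- dgp_config(n_fields = 60, seed = 1, beta0 = 3.79,
                    lat_slope = 0, sow_slope = 0, delta_fungicide = 0,
                    gamma_fung_sow = 0, gamma_fung_lat = 0,
                    ph_slope = 0, om_slope = 0, sigma = 0)
  sim <- simulate_fields(cfg)
  expect_equal(sim$fields$yield_t_ha, rep(3.79, 60))
  expect_equal(sim$truth$expected_yield, rep(3.79, 60))
})

test_that("marginal rates are calibrated at the survey size", {
  tbl <- simulate_fields(dgp_config(n_fields = 2738, seed = 9))$fields
  expect_lt(abs(mean(tbl$foliar_fungicide) - 0.304), 0.02)
  sprayed <- tbl$foliar_fungicide == 1
  expect_lt(abs(mean(tbl$foliar_insecticide[sprayed]) - 0.748), 0.03)
  counts <- sort(table(tbl$ted_id), decreasing = TRUE)
  expect_lt(abs(sum(counts[1:12]) / nrow(tbl) - 0.617), 0.03)
  expect_true(all(table(tbl$gdd_class) >= 0))
})

test_that("a pure main effect shows up as the sprayed-unsprayed mean difference", {
  cfg <- dgp_config(n_fields = 3000, seed = 21, delta_fungicide = 0.4,
                    gamma_fung_sow = 0, gamma_fung_lat = 0, sigma = 0.1)
  tbl <- simulate_fields(cfg)$fields
  a <- tbl$yield_t_ha[tbl$foliar_fungicide == 1]
  b <- tbl$yield_t_ha[tbl$foliar_fungicide == 0]
  # covariates are balanced across arms, so the contrast estimates delta;
  # allow 3 standard errors of the two-sample mean difference
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lt(abs((mean(a) - mean(b)) - 0.4), 3 * se)
})

test_that("the analytic fungicide Shapley oracle matches exhaustive enumeration", {
  sim <- small_sim(n = 40, seed = 13, sigma = 0)
  tbl <- sim$fields
  cf <- attr(sim$truth, "coefficients")
  # the true yield function, reduced to the three features touching fungicide
  f <- function(df) {
    cf$beta0 +
      cf$lat_slope * (df$latitude - cf$lat_center) +
      cf$sow_slope * (df$sowing_doy - cf$sow_center) +
      df$foliar_fungicide *
        (cf$delta_fungicide +
           cf$gamma_fung_sow * (df$sowing_doy - cf$sow_center) +
           cf$gamma_fung_lat * (df$latitude - cf$lat_center))
  }
  X <- as.data.frame(tbl)[, c("foliar_fungicide", "sowing_doy", "latitude")]
  ids <- tbl$field_id[c(1, 7, 25)]
  phi_closed <- true_shapley_fungicide(sim$truth, tbl, ids)
  for (k in seq_along(ids)) {
    phi_enum <- exhaustive_shapley(f, X, match(ids[k], tbl$field_id),
                                   "foliar_fungicide")
    expect_equal(unname(phi_closed[k]), phi_enum, tolerance = 1e-10)
  }
})

test_that("fungicide oracle: inert feature gives zero, pure main effect splits by spray rate", {
  sim0 <- small_sim(n = 50, seed = 2, delta_fungicide = 0,
                    gamma_fung_sow = 0, gamma_fung_lat = 0)
  expect_equal(unname(true_shapley_fungicide(sim0$truth, sim0$fields)),
               rep(0, 50))

  sim1 <- small_sim(n = 500, seed = 2, delta_fungicide = 0.4, p_spray = 0.5,
                    gamma_fung_sow = 0, gamma_fung_lat = 0)
  phi <- true_shapley_fungicide(sim1$truth, sim1$fields)
  p_hat <- mean(sim1$fields$foliar_fungicide)
  sprayed <- sim1$fields$foliar_fungicide == 1
  expect_equal(unname(phi[sprayed]), rep(0.4 * (1 - p_hat), sum(sprayed)))
  expect_equal(unname(phi[!sprayed]), rep(-0.4 * p_hat, sum(!sprayed)))
  # applied-treatment convention: zero stored contribution for unsprayed
  expect_true(all(sim1$truth$fungicide_contribution[!sprayed] == 0))
})

test_that("impossible probabilities are rejected", {
  expect_error(dgp_config(p_spray = 1.2), "probabilities")
  expect_error(dgp_config(sigma = -1), "sigma")
  expect_error(dgp_config(n_fields = 0), "n_fields")
})
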