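#' Net value and net profit of a fungicide-attributed yield change
#'
#' The fungicide Shapley value is on the yield scale (t/ha), so its market
#' value is `net_val = price * phi` (US$/ha) and the net profit after paying
#' for the chemical and its application is `net_profit = net_val - chem_cost`.
#' For unsprayed fields `chem_cost` is 0 by convention.
#'
#' @param phi Fungicide Shapley value(s), t/ha (vectorized).
#' @param price Soybean price, US$ per tonne.
#' @param chem_cost Combined chemical + application cost, US$ per hectare.
#' @return Data frame with columns `net_val` and `net_profit`, US$/ha.
#' @export
net_profit <- function(phi, price = 576.30, chem_cost = 61.90) {
  stopifnot(all(is.finite(phi)), price >= 0, chem_cost >= 0)
  nv <- price * phi
  data.frame(net_val = nv, net_profit = nv - chem_cost)
}

#' Break-even soybean price for a realized fungicide attribution
#'
#' Setting net profit to zero gives the minimum output price at which the
#' attributed yield gain pays for the intervention: `price0 = chem_cost / phi`
#' (US$/t). The break-even price falls nonlinearly as phi rises.
#'
#' @param phi Fungicide Shapley value(s), t/ha; must be strictly positive
#'   (no finite break-even price exists otherwise).
#' @param chem_cost Intervention cost, US$/ha.
#' @return Break-even price(s), US$ per tonne.
#' @export
break_even_price <- function(phi, chem_cost = 61.90) {
  if (any(phi <= 0)) {
    stop("break-even price is undefined for phi <= 0", call. = FALSE)
  }
  chem_cost / phi
}

#' BCa bootstrap confidence interval for a sample mean
#'
#' Bias-corrected and accelerated bootstrap interval: the bias correction z0
#' comes from the fraction of bootstrap means below the observed mean, the
#' acceleration from the jackknife skewness, and the interval endpoints are
#' the correspondingly adjusted percentiles of the bootstrap distribution.
#' Deterministic given the seed. A constant sample returns the degenerate
#' point interval (flagged via attribute `degenerate`).
#'
#' @param values Numeric sample (e.g. per-field net profits, US$/ha).
#' @param B Bootstrap replicates (>= 200).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List: `mean`, `ci_low`, `ci_high`, `B`, `level`.
#' @export
bca_ci <- function(values, B = 2000, level = 0.95, seed = 1) {
  n <- length(values)
  stopifnot(n >= 2, B >= 200, level > 0, level < 1)
  m <- mean(values)
  if (stats::sd(values) == 0) {
    return(structure(list(mean = m, ci_low = m, ci_high = m,
                          B = B, level = level), degenerate = TRUE))
  }
  set.seed(seed)
  boot_means <- colMeans(matrix(values[sample.int(n, n * B, replace = TRUE)],
                                nrow = n, ncol = B))
  # bias correction: position of the observed mean in the bootstrap distribution
  prop <- mean(boot_means < m)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))  # guard the probit
  z0 <- stats::qnorm(prop)
  # acceleration from jackknife influence values
  jack <- (sum(values) - values) / (n - 1)
  d <- mean(jack) - jack
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- (1 - level) / 2
  adj <- function(al) {
    z <- z0 + stats::qnorm(al)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  ci <- stats::quantile(boot_means, c(adj(alpha), adj(1 - alpha)),
                        names = FALSE, type = 7)
  list(mean = m, ci_low = ci[1], ci_high = ci[2], B = B, level = level)
}

#' Cohort-level economic summary
#'
#' Applies [net_profit()] to a cohort's fungicide attributions and summarizes
#' the mean net profit with a BCa bootstrap interval. For unsprayed cohorts
#' pass `chem_cost = 0`.
#'
#' @param phi Per-field fungicide Shapley values for the cohort, t/ha.
#' @param price,chem_cost Economics parameters (US$/t, US$/ha).
#' @param B,level,seed Passed to [bca_ci()].
#' @return List of class `"economic_result"`: `per_field` (data frame),
#'   `mean_net_profit`, `ci_low`, `ci_high`, `B`.
#' @export
cohort_economics <- function(phi, price = 576.30, chem_cost = 61.90,
                             B = 2000, level = 0.95, seed = 1) {
  pf <- net_profit(phi, price, chem_cost)
  ci <- if (length(phi) >= 2) {
    bca_ci(pf$net_profit, B = B, level = level, seed = seed)
  } else {
    # a single field has no sampling distribution to bootstrap
    list(mean = mean(pf$net_profit), ci_low = NA_real_, ci_high = NA_real_)
  }
  structure(list(per_field = pf, mean_net_profit = ci$mean,
                 ci_low = ci$ci_low, ci_high = ci$ci_high, B = B,
                 price = price, chem_cost = chem_cost),
            class = "economic_result")
}

#' @export
print.economic_result <- function(x, ...) {
  cat(sprintf("mean net profit US$%.2f/ha (95%% BCa CI %.2f to %.2f), n = %d, price %.2f, cost %.2f\n",
              x$mean_net_profit, x$ci_low, x$ci_high, nrow(x$per_field),
              x$price, x$chem_cost))
  invisible(x)
}

#' Yield gain attributable to rising fungicide adoption
#'
#' Converts a per-field mean yield gain among sprayed fields into an annual
#' region-level gain rate given a yearly increase in the adopted share of
#' hectarage, and expresses it as a share of the total annual yield gain:
#' `gain_rate = mean_gain * adoption_increase / 100`, and
#' `share = 100 * gain_rate / total_annual_gain`.
#'
#' @param mean_gain Mean fungicide-attributed gain among sprayed fields,
#'   kg/ha.
#' @param adoption_increase Yearly increase in the sprayed share of
#'   hectarage, percentage points per year.
#' @param total_annual_gain Total annual yield gain, kg/ha/yr (needed for
#'   `share`; pass `NULL` to skip).
#' @return List: `gain_rate` (kg/ha/yr) and `share` (\%, or `NA` if no total
#'   supplied).
#' @export
adoption_attribution <- function(mean_gain, adoption_increase,
                                 total_annual_gain = NULL) {
  stopifnot(mean_gain >= 0, adoption_increase >= 0)
  gain_rate <- mean_gain * adoption_increase / 100
  share <- if (is.null(total_annual_gain)) {
    NA_real_
  } else {
    if (total_annual_gain <= 0) {
      stop("total_annual_gain must be positive to compute a share",
           call. = FALSE)
    }
    100 * gain_rate / total_annual_gain
  }
  list(gain_rate = gain_rate, share = share)
}
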