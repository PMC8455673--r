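# Independent oracles used across tests. These deliberately use different
# algorithms from the package implementation.

# Exact Shapley value of `feature` for row `row_i` of `X` under the marginal
# (joint-background) value function, by weighted enumeration of all feature
# subsets: v(S) = mean over background rows of f(x_S, b_-S).
exhaustive_shapley <- function(f, X, row_i, feature,
                               features = names(X)) {
  p <- length(features)
  others <- setdiff(features, feature)
  phi <- 0
  for (mask in 0:(2^length(others) - 1)) {
    S <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
    w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
    v <- function(cols) {
      hyb <- X
      for (cl in cols) hyb[[cl]] <- X[[cl]][row_i]
      mean(f(hyb))
    }
    phi <- phi + w * (v(c(S, feature)) - v(S))
  }
  phi
}

# Closed-form Welch comparison (estimate, Satterthwaite df, CI bounds).
welch_oracle <- function(a, b, level = 0.95) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  est <- mean(a) - mean(b)
  hw <- qt(1 - (1 - level) / 2, df) * sqrt(va + vb)
  list(estimate = est, df = df, ci_low = est - hw, ci_high = est + hw)
}

# A transparent linear "model" usable wherever a yield_forest is expected:
# predict() evaluates a fixed linear+interaction function of named columns.
linear_model <- function(fun, predictor_names, global_mean = 0) {
  structure(list(fun = fun, predictor_names = predictor_names,
                 factor_levels = list(), global_mean_prediction = global_mean),
            class = c("linear_test_model", "yield_forest"))
}

predict.linear_test_model <- function(object, newdata, ...) {
  object$fun(as.data.frame(newdata))
}
registerS3method("predict", "linear_test_model", predict.linear_test_model,
                 envir = asNamespace("stats"))

# Small default synthetic table for cheap tests.
small_sim <- function(n = 400, seed = 11, ...) {
  simulate_fields(dgp_config(n_fields = n, seed = seed, ...))
}
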