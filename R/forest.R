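#' Split a field table into training and test sets
#'
#' Simple random split without stratification. The training set holds
#' `ceiling(fraction * n)` rows; the two parts are disjoint and exhaust the
#' table, and the split is reproducible from the seed.
#'
#' @param table A `field_table`.
#' @param fraction Training proportion in (0, 1); default 0.8 (an 80:20
#'   split).
#' @param seed Integer seed.
#' @return List with `train` and `test` field tables.
#' @export
split_train_test <- function(table, fraction = 0.8, seed = 1) {
  stopifnot(fraction > 0, fraction < 1, nrow(table) > 0)
  n <- nrow(table)
  n_train <- ceiling(fraction * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  prov <- attr(table, "provenance")
  list(
    train = field_table(as.data.frame(table)[sort(idx), , drop = FALSE],
                        predictors = predictors(table),
                        lat_range = c(-90, 90), provenance = prov),
    test = field_table(as.data.frame(table)[-sort(idx), , drop = FALSE],
                       predictors = predictors(table),
                       lat_range = c(-90, 90), provenance = prov)
  )
}

#' Tune random-forest hyperparameters by out-of-bag error
#'
#' Budgeted random search over `min.node.size`, `sample.fraction` and `mtry`,
#' minimizing out-of-bag mean-squared error. Trees are grown on samples drawn
#' without replacement. The full evaluation log is retained so the chosen
#' triple can be audited: the returned candidate is exactly the OOB-best among
#' those evaluated.
#'
#' @param train Training `field_table`.
#' @param budget Number of candidate triples to evaluate.
#' @param min_node_size_range,sample_fraction_range,mtry_range Inclusive
#'   search ranges.
#' @param n_trees Trees per candidate fit (smaller than the final fit is
#'   fine; OOB error ranks candidates stably).
#' @param seed Integer seed (controls both candidate draws and fits).
#' @return List of class `"forest_tuning"`: `best` (named list
#'   `min_node_size`, `sample_fraction`, `mtry`), `oob_mse` of the best, and
#'   `log` (data frame of all evaluations).
#' @export
tune_yield_forest <- function(train, budget = 20,
                              min_node_size_range = c(1, 20),
                              sample_fraction_range = c(0.3, 1),
                              mtry_range = c(1, 20),
                              n_trees = 500, seed = 1) {
  stopifnot(budget >= 1, nrow(train) > 0)
  preds <- predictors(train)
  mtry_hi <- min(mtry_range[2], length(preds))
  set.seed(seed)
  cand <- data.frame(
    min_node_size = sample(seq(min_node_size_range[1], min_node_size_range[2]),
                           budget, replace = TRUE),
    sample_fraction = stats::runif(budget, sample_fraction_range[1],
                                   sample_fraction_range[2]),
    mtry = sample(seq(mtry_range[1], mtry_hi), budget, replace = TRUE)
  )
  cand$oob_mse <- NA_real_
  for (i in seq_len(budget)) {
    fit <- ranger::ranger(
      x = as.data.frame(train)[, preds, drop = FALSE],
      y = train$yield_t_ha,
      num.trees = n_trees,
      mtry = cand$mtry[i],
      min.node.size = cand$min_node_size[i],
      sample.fraction = cand$sample_fraction[i],
      replace = FALSE,
      seed = seed + i,
      num.threads = 1
    )
    cand$oob_mse[i] <- fit$prediction.error
  }
  best <- which.min(cand$oob_mse)
  structure(list(best = list(min_node_size = cand$min_node_size[best],
                             sample_fraction = cand$sample_fraction[best],
                             mtry = cand$mtry[best]),
                 oob_mse = cand$oob_mse[best],
                 log = cand),
            class = "forest_tuning")
}

#' Fit the random-forest yield model
#'
#' The central fitting function: grows a regression forest of `n_trees` trees
#' (default 3000, large for stability of permutation-based importance) on the
#' supplied table, sampling without replacement, and caches the global mean
#' prediction — the reference point for all Shapley attributions. Prediction
#' from the fitted object is deterministic.
#'
#' @param train `field_table` to fit on (after test-set evaluation the model
#'   is conventionally refit to the full matrix).
#' @param params Hyperparameter triple as returned in `tune_yield_forest()$best`;
#'   `NULL` uses ranger defaults (mtry = floor(sqrt(p)), min.node.size = 5,
#'   sample.fraction = 0.8).
#' @param n_trees Number of trees.
#' @param seed Integer seed for tree growing.
#' @return Object of class `"yield_forest"`.
#' @export
yield_forest <- function(train, params = NULL, n_trees = 3000, seed = 1) {
  preds <- predictors(train)
  if (is.null(params)) {
    params <- list(min_node_size = 5, sample_fraction = 0.8,
                   mtry = max(1, floor(sqrt(length(preds)))))
  }
  if (params$min_node_size > nrow(train)) {
    stop("min_node_size exceeds the number of training rows", call. = FALSE)
  }
  fit <- ranger::ranger(
    x = as.data.frame(train)[, preds, drop = FALSE],
    y = train$yield_t_ha,
    num.trees = n_trees,
    mtry = min(params$mtry, length(preds)),
    min.node.size = params$min_node_size,
    sample.fraction = params$sample_fraction,
    replace = FALSE,
    seed = seed,
    num.threads = 1
  )
  obj <- structure(list(forest = fit,
                        n_trees = n_trees,
                        tuned_params = params,
                        predictor_names = preds,
                        train_ids = train$field_id,
                        factor_levels = lapply(
                          as.data.frame(train)[, preds, drop = FALSE],
                          function(col) if (is.factor(col)) levels(col) else NULL),
                        global_mean_prediction = NA_real_,
                        seed = seed),
                   class = "yield_forest")
  obj$global_mean_prediction <- mean(predict(obj, train))
  obj
}

#' Predict yields from a fitted yield forest
#'
#' @param object A `yield_forest`.
#' @param newdata A `field_table` or data frame containing the model's
#'   predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted yields, t/ha.
#' @export
predict.yield_forest <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)[, object$predictor_names, drop = FALSE]
  for (col in names(object$factor_levels)) {
    lv <- object$factor_levels[[col]]
    if (!is.null(lv)) df[[col]] <- factor(as.character(df[[col]]), levels = lv)
  }
  ranger::predictions(stats::predict(object$forest, data = df,
                                     num.threads = 1))
}

#' @export
print.yield_forest <- function(x, ...) {
  cat(sprintf("yield_forest: %d trees, %d predictors, %d training fields\n",
              x$n_trees, length(x$predictor_names), length(x$train_ids)))
  cat(sprintf("  mtry = %d, min.node.size = %d, sample.fraction = %.3f (no replacement)\n",
              x$tuned_params$mtry, x$tuned_params$min_node_size,
              x$tuned_params$sample_fraction))
  cat(sprintf("  global mean prediction: %.3f t/ha\n",
              x$global_mean_prediction))
  invisible(x)
}

#' Fit diagnostics for a yield forest
#'
#' Residuals (predicted minus observed), RMSE, the proportion of residuals
#' within a tolerance band, and summary statistics of the prediction
#' distribution. Random forests shrink toward the mean, so expect
#' overprediction at low observed yields and underprediction at the high end.
#'
#' @param model A `yield_forest`.
#' @param table `field_table` to evaluate on.
#' @param resid_threshold Band half-width for `frac_abs_resid_le`, t/ha.
#' @return List of class `"forest_diagnostics"`.
#' @export
forest_diagnostics <- function(model, table, resid_threshold = 0.25) {
  stopifnot(nrow(table) > 0)
  pred <- predict(model, table)
  resid <- pred - table$yield_t_ha
  structure(list(rmse = sqrt(mean(resid^2)),
                 residuals = stats::setNames(resid, table$field_id),
                 resid_threshold = resid_threshold,
                 frac_abs_resid_le = mean(abs(resid) <= resid_threshold),
                 pred_min = min(pred), pred_max = max(pred),
                 pred_mean = mean(pred), pred_sd = stats::sd(pred)),
            class = "forest_diagnostics")
}

#' @export
print.forest_diagnostics <- function(x, ...) {
  cat(sprintf("RMSE %.3f t/ha; %.1f%% of |residuals| <= %.2f t/ha\n",
              x$rmse, 100 * x$frac_abs_resid_le, x$resid_threshold))
  cat(sprintf("predictions: mean %.2f, sd %.2f, range [%.2f, %.2f] t/ha\n",
              x$pred_mean, x$pred_sd, x$pred_min, x$pred_max))
  invisible(x)
}

#' @export
residuals.yield_forest <- function(object, table, ...) {
  predict(object, table) - table$yield_t_ha
}

#' @export
summary.yield_forest <- function(object, table = NULL, ...) {
  print(object)
  if (!is.null(table)) print(forest_diagnostics(object, table))
  invisible(object)
}

#' Residuals-versus-predicted diagnostic plot
#'
#' @param x A `yield_forest`.
#' @param table `field_table` to evaluate on.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.yield_forest <- function(x, table, ...) {
  pred <- predict(x, table)
  graphics::plot(pred, pred - table$yield_t_ha,
                 xlab = "predicted yield (t/ha)",
                 ylab = "predicted - observed (t/ha)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
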