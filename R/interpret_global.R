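#' Permutation feature importance as an error ratio
#'
#' For each predictor, the values of that column alone are shuffled and the
#' model's mean absolute error (MAE) on the perturbed table is compared with
#' the original error: FI = err_permuted / err_original. A predictor the
#' model does not use has FI = 1; informative predictors have FI > 1.
#' Shuffling is repeated `reps` times (default 20) and summarized by the
#' median and the 5\%/95\% quantiles. Per-(feature, rep) shuffle seeds are
#' recorded so any single ratio can be replayed exactly.
#'
#' @param model A `yield_forest`.
#' @param table `field_table` to measure loss on (conventionally the full
#'   matrix the final model was refit to).
#' @param reps Number of repeated shuffles per feature.
#' @param seed Integer master seed.
#' @param features Predictors to assess (default: all the model's).
#' @return Data frame of class `"feature_importance"` with columns `feature`,
#'   `fi_median`, `fi_q05`, `fi_q95`, sorted by descending median; the full
#'   reps-by-features ratio matrix is attached as attribute `samples` and the
#'   shuffle seeds as `seeds`.
#' @export
permutation_importance <- function(model, table, reps = 20, seed = 1,
                                   features = model$predictor_names) {
  stopifnot(reps >= 1)
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0) {
    stop("feature(s) absent from table: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(table)
  obs <- table$yield_t_ha
  err_o <- mean(abs(predict(model, df) - obs))
  n <- nrow(df)
  samples <- matrix(NA_real_, nrow = reps, ncol = length(features),
                    dimnames = list(NULL, features))
  seeds <- matrix(NA_integer_, nrow = reps, ncol = length(features),
                  dimnames = list(NULL, features))
  for (j in seq_along(features)) {
    f <- features[j]
    for (r in seq_len(reps)) {
      s <- (seed * 1009L + j * 131L + r) %% .Machine$integer.max
      seeds[r, j] <- s
      set.seed(s)
      perm <- sample.int(n)
      df2 <- df
      df2[[f]] <- df[[f]][perm]
      err_p <- mean(abs(predict(model, df2) - obs))
      samples[r, j] <- err_p / err_o
    }
  }
  out <- data.frame(
    feature = features,
    fi_median = apply(samples, 2, stats::median),
    fi_q05 = apply(samples, 2, stats::quantile, probs = 0.05),
    fi_q95 = apply(samples, 2, stats::quantile, probs = 0.95),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(-out$fi_median, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("feature_importance", "data.frame"),
            samples = samples, seeds = seeds, err_original = err_o)
}

#' Replay one permutation-importance ratio from its recorded seed
#'
#' Recomputes a single (feature, rep) FI ratio from the seed stored on a
#' [permutation_importance()] result, for audit.
#'
#' @param fi A `feature_importance` object.
#' @param model,table The model and table the ratios were computed on.
#' @param feature Feature name.
#' @param rep Repetition index.
#' @return The recomputed FI ratio (a single number).
#' @export
replay_fi <- function(fi, model, table, feature, rep) {
  seeds <- attr(fi, "seeds")
  df <- as.data.frame(table)
  obs <- table$yield_t_ha
  err_o <- mean(abs(predict(model, df) - obs))
  set.seed(seeds[rep, feature])
  perm <- sample.int(nrow(df))
  df[[feature]] <- df[[feature]][perm]
  mean(abs(predict(model, df) - obs)) / err_o
}

#' Two-way partial-dependence difference curve for a binary intervention
#'
#' Evaluates the model's partial dependence on the joint setting of a binary
#' feature (e.g. foliar fungicide use) and a continuous co-feature (sowing
#' day or latitude): PD(f, v) is the mean prediction over all table rows with
#' the binary feature forced to `f` and the co-feature to `v`. The
#' `difference` curve PD(1, v) - PD(0, v) is the model's global estimate of
#' the intervention's yield effect as a function of the co-feature; a
#' loess-smoothed version is attached.
#'
#' @param model A `yield_forest`.
#' @param table `field_table` providing the background distribution.
#' @param binary_feature Name of the binary column (must take exactly the
#'   values 0 and 1 in `table`).
#' @param co_feature Name of the numeric co-feature.
#' @param grid_size Number of equally spaced grid points spanning the
#'   observed range of the co-feature (no extrapolation).
#' @param span Smoother span for the lowess-smoothed difference.
#' @return List of class `"interaction_curve"`: `grid`, `pd_sprayed`,
#'   `pd_unsprayed`, `difference`, `smoothed_difference`.
#' @export
pd_difference <- function(model, table, binary_feature = "foliar_fungicide",
                          co_feature, grid_size = 40, span = 0.5) {
  vals <- sort(unique(as.data.frame(table)[[binary_feature]]))
  if (!identical(as.numeric(vals), c(0, 1))) {
    stop(sprintf("'%s' is not binary 0/1 in this table", binary_feature),
         call. = FALSE)
  }
  z <- as.data.frame(table)[[co_feature]]
  if (!is.numeric(z)) stop("co_feature must be numeric", call. = FALSE)
  grid <- seq(min(z), max(z), length.out = grid_size)
  df <- as.data.frame(table)
  pd <- function(f, v) {
    df[[binary_feature]] <- f
    df[[co_feature]] <- v
    mean(predict(model, df))
  }
  pd1 <- vapply(grid, function(v) pd(1L, v), numeric(1))
  pd0 <- vapply(grid, function(v) pd(0L, v), numeric(1))
  diff <- pd1 - pd0
  sm <- stats::lowess(grid, diff, f = span)$y
  structure(list(grid = grid, pd_sprayed = pd1, pd_unsprayed = pd0,
                 difference = diff, smoothed_difference = sm,
                 binary_feature = binary_feature, co_feature = co_feature),
            class = "interaction_curve")
}

#' @export
print.interaction_curve <- function(x, ...) {
  cat(sprintf("PD difference of '%s' along '%s': %d grid points, difference %.3f to %.3f t/ha\n",
              x$binary_feature, x$co_feature, length(x$grid),
              min(x$difference), max(x$difference)))
  invisible(x)
}

#' @export
plot.interaction_curve <- function(x, ...) {
  graphics::plot(x$grid, x$difference, type = "l",
                 xlab = x$co_feature,
                 ylab = sprintf("PD(%s=1) - PD(%s=0), t/ha",
                                x$binary_feature, x$binary_feature), ...)
  graphics::lines(x$grid, x$smoothed_difference, col = "blue", lwd = 2)
  invisible(x)
}
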