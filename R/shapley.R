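# Per-field seed derived from the master seed and the field id, so results
# for a field do not depend on evaluation order or parallel scheduling.
field_seed <- function(seed, field_id) {
  h <- sum(utf8ToInt(field_id) * seq_along(utf8ToInt(field_id)))
  as.integer((seed * 48271 + h * 131) %% .Machine$integer.max)
}

#' Monte-Carlo Shapley attribution for one field
#'
#' Estimates, for each requested feature, how much that feature contributed
#' to the difference between the field's predicted yield and the global mean
#' prediction (the Shapley value, in t/ha). Per iteration a background row is
#' drawn uniformly from the table and a uniform random feature ordering is
#' drawn; for each feature two hybrid rows are formed that are identical
#' except for the target feature (taken from the field of interest versus
#' from the background row), with features preceding the target in the
#' ordering taken from the field of interest and the rest from the
#' background. The prediction difference between the two hybrids is the
#' feature's marginal contribution for that iteration; phi is the mean over
#' iterations and `mc_se` the Monte-Carlo standard error.
#'
#' The background row and ordering are shared across features within an
#' iteration, so when all features are requested the contributions telescope
#' and their sum equals prediction(field) minus the mean prediction of the
#' sampled backgrounds; the `efficiency_residual` (prediction - global_mean -
#' sum of phi) therefore shrinks stochastically as `n_iter` grows.
#'
#' @param model A `yield_forest`.
#' @param table `field_table` supplying the empirical background
#'   distribution (conventionally the full data matrix).
#' @param field_id Field to explain.
#' @param features Features to attribute (default: all model predictors).
#' @param n_iter Monte-Carlo iterations (the reference analysis uses 1000
#'   per field).
#' @param seed Master integer seed; the effective per-field seed is derived
#'   from it and the field id.
#' @return Data frame of class `"shapley_attribution"` with columns
#'   `field_id`, `feature`, `phi`, `mc_se`, `n_iter`, `prediction`,
#'   `global_mean`; attribute `efficiency_residual` is set when all model
#'   features were attributed.
#' @export
mc_shapley <- function(model, table, field_id,
                       features = model$predictor_names,
                       n_iter = 1000, seed = 1) {
  stopifnot(n_iter >= 1)
  preds <- model$predictor_names
  bad <- setdiff(features, preds)
  if (length(bad) > 0) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  row_i <- match(field_id, table$field_id)
  if (is.na(row_i)) stop("unknown field id: ", field_id, call. = FALSE)

  df <- as.data.frame(table)[, preds, drop = FALSE]
  # work on character values for factors; predict() re-levels them
  cols <- lapply(df, function(col) if (is.factor(col)) as.character(col) else col)
  x_i <- lapply(cols, function(col) col[row_i])
  p <- length(preds)

  set.seed(field_seed(seed, field_id))
  bg <- sample.int(nrow(df), n_iter, replace = TRUE)
  # pos[t, c]: position of predictor c in iteration t's random ordering
  pos <- t(vapply(seq_len(n_iter), function(t) {
    perm <- sample.int(p)
    o <- integer(p); o[perm] <- seq_len(p); o
  }, integer(p)))
  colnames(pos) <- preds

  build_rows <- function(mask) {
    # mask: n_iter x p logical; TRUE -> value from field of interest
    out <- vector("list", p)
    names(out) <- preds
    for (c in preds) {
      v <- cols[[c]][bg]
      v[mask[, c]] <- x_i[[c]]
      out[[c]] <- v
    }
    as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  }

  blocks <- vector("list", length(features))
  for (k in seq_along(features)) {
    j <- features[k]
    mask_with <- pos <= pos[, j]       # features at or before j in the ordering
    mask_without <- mask_with
    mask_without[, j] <- FALSE
    blocks[[k]] <- rbind(build_rows(mask_with), build_rows(mask_without))
  }
  all_rows <- do.call(rbind, blocks)
  pred_all <- predict(model, all_rows)

  prediction <- predict(model, df[row_i, , drop = FALSE])
  phi <- numeric(length(features))
  mc_se <- numeric(length(features))
  diffs_sum <- numeric(n_iter)
  for (k in seq_along(features)) {
    off <- (k - 1) * 2 * n_iter
    d <- pred_all[off + seq_len(n_iter)] -
      pred_all[off + n_iter + seq_len(n_iter)]
    phi[k] <- mean(d)
    mc_se[k] <- stats::sd(d) / sqrt(n_iter)
    diffs_sum <- diffs_sum + d
  }

  out <- data.frame(field_id = field_id, feature = features,
                    phi = phi, mc_se = mc_se, n_iter = n_iter,
                    prediction = prediction,
                    global_mean = model$global_mean_prediction,
                    stringsAsFactors = FALSE)
  eff <- if (setequal(features, preds)) {
    prediction - model$global_mean_prediction - sum(phi)
  } else NA_real_
  structure(out, class = c("shapley_attribution", "data.frame"),
            efficiency_residual = eff)
}

#' Fungicide Shapley values for a set of fields
#'
#' Convenience wrapper computing the foliar-fungicide attribution for many
#' fields (e.g. a cohort); one row per field.
#'
#' @param model,table,n_iter,seed As in [mc_shapley()].
#' @param field_ids Fields to attribute.
#' @param feature Feature to attribute (default the fungicide flag).
#' @return Data frame: `field_id`, `feature`, `phi`, `mc_se`, `prediction`,
#'   `global_mean`, plus `sprayed` (the field's own flag) and the
#'   interpretation `label` from [interpret_phi()].
#' @export
shapley_fungicide <- function(model, table, field_ids,
                              feature = "foliar_fungicide",
                              n_iter = 1000, seed = 1) {
  res <- lapply(field_ids, function(id) {
    mc_shapley(model, table, id, features = feature,
               n_iter = n_iter, seed = seed)
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out$sprayed <- table$foliar_fungicide[match(out$field_id, table$field_id)] == 1
  out$label <- mapply(interpret_phi, out$phi, out$sprayed)
  out
}

#' Agronomic interpretation of a fungicide Shapley value
#'
#' Maps the sign of the fungicide phi and the field's spray status to its
#' agronomic meaning. For a sprayed field a positive phi is yield gained from
#' spraying and a negative phi a loss despite (or due to) spraying. For an
#' unsprayed field a negative phi estimates how much yield was penalized by
#' not applying a foliar fungicide, while a positive phi would
#' (counterintuitively) indicate yield benefited from not spraying.
#'
#' @param phi Fungicide Shapley value, t/ha.
#' @param sprayed Logical: was the field sprayed?
#' @return One of `"gain-from-spray"`, `"loss-from-spray"`,
#'   `"benefit-from-not-spraying"`, `"penalty-for-not-spraying"`,
#'   `"no-effect"`.
#' @export
interpret_phi <- function(phi, sprayed) {
  if (phi == 0) return("no-effect")
  if (sprayed) {
    if (phi > 0) "gain-from-spray" else "loss-from-spray"
  } else {
    if (phi > 0) "benefit-from-not-spraying" else "penalty-for-not-spraying"
  }
}

#' @export
print.shapley_attribution <- function(x, ...) {
  eff <- attr(x, "efficiency_residual")
  cat(sprintf("Shapley attribution for field %s (prediction %.3f, global mean %.3f t/ha)\n",
              x$field_id[1], x$prediction[1], x$global_mean[1]))
  print.data.frame(x[order(-abs(x$phi)), c("feature", "phi", "mc_se")],
                   row.names = FALSE, digits = 4)
  if (!is.na(eff)) cat(sprintf("efficiency residual: %.4f t/ha\n", eff))
  invisible(x)
}
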