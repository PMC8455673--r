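#' Welch two-sample comparison of yields
#'
#' Unequal-variance (Welch) estimate of the mean yield difference between two
#' groups of fields, with a Satterthwaite-approximated confidence interval.
#' The emphasis is on the effect size and its interval rather than on a
#' p-value: with thousands of fields even agronomically trivial differences
#' are "significant".
#'
#' @param yields_a,yields_b Numeric yield vectors (t/ha); the estimate is
#'   mean(a) - mean(b).
#' @param level Confidence level.
#' @return List of class `"two_sample_result"`: `estimate`, `ci_low`,
#'   `ci_high`, `n1`, `n2`, `df`.
#' @export
welch_t <- function(yields_a, yields_b, level = 0.95) {
  if (length(yields_a) < 2) stop("group 'a' needs >= 2 observations",
                                 call. = FALSE)
  if (length(yields_b) < 2) stop("group 'b' needs >= 2 observations",
                                 call. = FALSE)
  if (stats::var(yields_a) + stats::var(yields_b) == 0) {
    stop("both groups are constant; Welch comparison is degenerate",
         call. = FALSE)
  }
  tt <- stats::t.test(yields_a, yields_b, var.equal = FALSE,
                      conf.level = level)
  structure(list(estimate = unname(diff(rev(tt$estimate))),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 n1 = length(yields_a), n2 = length(yields_b),
                 df = unname(tt$parameter)),
            class = "two_sample_result")
}

#' The k most-populous TEDs of a table
#'
#' Ranking is by field count, ties broken lexicographically by TED id for
#' reproducibility.
#'
#' @param table A `field_table`.
#' @param k Number of TEDs to return (fewer if the table has fewer).
#' @return Character vector of TED ids, largest first.
#' @export
top_teds <- function(table, k = 12) {
  counts <- table(table$ted_id)
  ord <- order(-as.integer(counts), names(counts))
  utils::head(names(counts)[ord], k)
}

#' Per-TED sprayed-vs-unsprayed yield comparisons
#'
#' Applies [welch_t()] within each of the `k` most-populous TEDs. TEDs with
#' fewer than 2 sprayed or 2 unsprayed fields are skipped with a warning.
#'
#' @param table A `field_table`.
#' @param k Number of most-populous TEDs to test.
#' @param level Confidence level.
#' @return Named list of `two_sample_result`, keyed by TED id.
#' @export
per_ted_t <- function(table, k = 12, level = 0.95) {
  stopifnot(k >= 1)
  out <- list()
  for (ted in top_teds(table, k)) {
    sub <- table[table$ted_id == ted, ]
    a <- sub$yield_t_ha[sub$foliar_fungicide == 1]
    b <- sub$yield_t_ha[sub$foliar_fungicide == 0]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("TED %s skipped: %d sprayed / %d unsprayed fields",
                      ted, length(a), length(b)), call. = FALSE)
      next
    }
    out[[ted]] <- welch_t(a, b, level = level)
  }
  out
}

#' Mixed-model estimate of the fungicide effect across TEDs
#'
#' Fits, by maximum likelihood, a linear mixed model of yield on foliar
#' fungicide use with random intercepts and (optionally) random fungicide
#' slopes within TEDs. The random-slopes model allows the fungicide effect to
#' vary across production environments; comparing its AIC against the
#' intercept-only reduction indicates whether that heterogeneity is supported
#' by the data.
#'
#' @param table A `field_table`.
#' @param random_slopes Fit random fungicide slopes within TEDs (`TRUE`) or
#'   the random-intercept-only reduction (`FALSE`).
#' @return List of class `"mixed_model_result"`: `fungicide_effect` (t/ha),
#'   `model_fit_score` (AIC; lower is better), `converged`, `n_groups`, and
#'   the underlying `fit`.
#' @export
fit_fungicide_mixed <- function(table, random_slopes = TRUE) {
  both <- tapply(table$foliar_fungicide, table$ted_id,
                 function(f) any(f == 1) && any(f == 0))
  if (sum(both, na.rm = TRUE) < 2) {
    stop("need >= 2 TEDs containing both sprayed and unsprayed fields",
         call. = FALSE)
  }
  df <- data.frame(yield = table$yield_t_ha,
                   fung = table$foliar_fungicide,
                   ted = factor(table$ted_id))
  form <- if (random_slopes) yield ~ fung + (1 + fung | ted)
          else yield ~ fung + (1 | ted)
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = FALSE))
  conv <- fit@optinfo$conv$opt == 0  # singular random effects are tolerated
  structure(list(fungicide_effect = unname(lme4::fixef(fit)["fung"]),
                 model_fit_score = stats::AIC(fit),
                 converged = conv,
                 n_groups = nlevels(df$ted),
                 fit = fit),
            class = "mixed_model_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf("yield difference: %.3f t/ha (%.0f%% CI %.3f to %.3f), n = %d/%d, df = %.1f\n",
              x$estimate, 95, x$ci_low, x$ci_high, x$n1, x$n2, x$df))
  invisible(x)
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("mixed-model fungicide effect: %.3f t/ha (AIC %.1f, %d TEDs%s)\n",
              x$fungicide_effect, x$model_fit_score, x$n_groups,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
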