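#' Configuration of the synthetic survey-data generating process
#'
#' The generator emulates the structure of a grower survey of non-irrigated
#' soybean fields in the U.S. north-central region: a latitudinal
#' yield/maturity gradient, a delayed-sowing penalty, soil effects, a binary
#' foliar-fungicide intervention with interactions (larger benefit when sown
#' late, smaller benefit further north), skewed TED membership, and realistic
#' adoption rates. The yield process is additive plus fungicide-by-covariate
#' interactions with Gaussian noise, so the fungicide's true attribution is
#' known in closed form for every field.
#'
#' Defaults are the study conditions the pipeline is calibrated to: 2738
#' fields, 30.4\% fungicide adoption, 74.8\% insecticide co-application among
#' sprayed fields, 96 TEDs with the largest 12 holding 61.7\% of rows, a
#' fungicide main effect of 0.33 t/ha, and a residual standard deviation of
#' 0.30 t/ha.
#'
#' @param n_fields Number of fields to generate.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param beta0 Baseline yield, t/ha, at the covariate centers for an
#'   unsprayed field.
#' @param lat_slope Yield change per degree latitude (negative: yield
#'   declines northward), t/ha per degree.
#' @param sow_slope Yield change per day of sowing delay (negative), t/ha
#'   per day.
#' @param delta_fungicide Fungicide main effect at the covariate centers,
#'   t/ha.
#' @param gamma_fung_sow Fungicide x sowing-day interaction (positive:
#'   larger benefit when sown late), t/ha per day.
#' @param gamma_fung_lat Fungicide x latitude interaction (negative: smaller
#'   benefit northward), t/ha per degree.
#' @param ph_slope,om_slope Soil effects, t/ha per pH unit and per \% organic
#'   matter (both centered).
#' @param sigma Residual standard deviation, t/ha (may be 0 for a noiseless
#'   process).
#' @param p_spray Marginal probability a field is sprayed with foliar
#'   fungicide.
#' @param p_insecticide_given_spray Probability of foliar insecticide
#'   co-application on a fungicide-sprayed field.
#' @param p_insecticide_unsprayed Insecticide probability on unsprayed
#'   fields.
#' @param n_teds Number of technology extrapolation domains.
#' @param ted_top12_share Target share of rows held by the 12 most-populous
#'   TEDs; the TED size distribution is a power law whose exponent is solved
#'   to hit this share in expectation.
#' @param confounding Logit-scale tilt of spray probability with the field's
#'   non-fungicide expected yield (0 = randomized adoption, the default).
#' @param lat_range Latitude band of the study region, degrees N.
#' @param lat_center,sow_center,ph_center,om_center Centering constants for
#'   the linear terms.
#' @return A list of class `"dgp_config"`.
#' @export
dgp_config <- function(n_fields = 2738, seed = 1,
                       beta0 = 3.69,
                       lat_slope = -0.12, sow_slope = -0.02,
                       delta_fungicide = 0.33,
                       gamma_fung_sow = 0.004, gamma_fung_lat = -0.02,
                       ph_slope = 0.08, om_slope = 0.04,
                       sigma = 0.30,
                       p_spray = 0.304,
                       p_insecticide_given_spray = 0.748,
                       p_insecticide_unsprayed = 0.05,
                       n_teds = 96, ted_top12_share = 0.617,
                       confounding = 0,
                       lat_range = c(37, 49),
                       lat_center = 43, sow_center = 140,
                       ph_center = 6.5, om_center = 3) {
  cfg <- as.list(environment())
  probs <- c(cfg$p_spray, cfg$p_insecticide_given_spray,
             cfg$p_insecticide_unsprayed, cfg$ted_top12_share)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (cfg$n_fields < 1) stop("n_fields must be positive", call. = FALSE)
  if (cfg$n_teds < 13) stop("need more than 12 TEDs", call. = FALSE)
  class(cfg) <- "dgp_config"
  cfg
}

# Power-law TED size distribution p_i ~ i^(-a); a is solved so the 12
# largest TEDs hold the target share of rows in expectation.
ted_size_probs <- function(n_teds, top12_share) {
  share <- function(a) {
    p <- (1:n_teds)^(-a)
    sum(p[1:12]) / sum(p)
  }
  a <- stats::uniroot(function(a) share(a) - top12_share,
                      interval = c(1e-6, 10))$root
  p <- (1:n_teds)^(-a)
  p / sum(p)
}

# Monotone latitude -> growing-degree-day class lookup. Class numbers rise
# with accumulated thermal units, so southerly (low-latitude) fields carry
# the higher class labels.
gdd_class_of_latitude <- function(lat) {
  cut(lat, breaks = c(-Inf, 39.5, 43.5, 46, 48, Inf),
      labels = c("05", "04", "03", "02", "01"), right = FALSE)
}

mg_of_latitude <- function(lat) {
  cut(lat, breaks = c(-Inf, 41, 43.5, 45.5, 47.3, Inf),
      labels = c("IV", "III", "II", "I", "0"), right = FALSE)
}

#' Generate a synthetic field table with known ground truth
#'
#' Draws a survey-structured table of soybean fields from the configured
#' yield process. The returned ground truth carries each field's noiseless
#' expected yield, the fungicide contribution evaluated at that field's
#' covariates (zero for unsprayed fields under the applied-treatment
#' convention), and the full coefficient vector, so that attribution
#' estimators can be validated against closed-form values.
#'
#' @param config A [dgp_config()].
#' @return List with elements `fields` (a validated `field_table`) and
#'   `truth` (data frame: `field_id`, `expected_yield`,
#'   `fungicide_contribution`, with the coefficients and covariate moments
#'   attached as attributes).
#' @export
simulate_fields <- function(config = dgp_config()) {
  stopifnot(inherits(config, "dgp_config"))
  cfg <- config
  n <- cfg$n_fields
  rng <- local({
    set.seed(cfg$seed)
    NULL
  })

  ted_probs <- ted_size_probs(cfg$n_teds, cfg$ted_top12_share)
  ted_idx <- sample.int(cfg$n_teds, n, replace = TRUE, prob = ted_probs)
  # TED centers concentrated mid-band (corn-belt style density)
  ted_lat <- cfg$lat_range[1] + 0.5 +
    (diff(cfg$lat_range) - 1) * stats::rbeta(cfg$n_teds, 2.2, 2.2)
  ted_aridity <- sprintf("%02d", sample.int(5, cfg$n_teds, replace = TRUE,
                                            prob = c(0.1, 0.2, 0.35, 0.25, 0.1)))
  ted_pawr <- sprintf("%02d", sample.int(7, cfg$n_teds, replace = TRUE))

  latitude <- pmin(pmax(ted_lat[ted_idx] + stats::rnorm(n, 0, 0.6),
                        cfg$lat_range[1]), cfg$lat_range[2])
  longitude <- round(stats::runif(n, -104, -82), 3)
  sowing_doy <- as.integer(round(pmin(pmax(
    cfg$sow_center + 1.8 * (latitude - cfg$lat_center) + stats::rnorm(n, 0, 9),
    95), 180)))
  soil_ph <- round(pmin(pmax(stats::rnorm(n, 6.6, 0.45), 5), 8), 2)
  soil_om <- round(pmin(pmax(exp(stats::rnorm(n, log(3), 0.3)), 0.5), 10), 2)

  latc <- latitude - cfg$lat_center
  sowc <- sowing_doy - cfg$sow_center
  base_eta <- cfg$beta0 + cfg$lat_slope * latc + cfg$sow_slope * sowc +
    cfg$ph_slope * (soil_ph - cfg$ph_center) +
    cfg$om_slope * (soil_om - cfg$om_center)

  p_spray_i <- if (cfg$confounding == 0) {
    rep(cfg$p_spray, n)
  } else {
    stats::plogis(stats::qlogis(cfg$p_spray) +
                    cfg$confounding * (base_eta - mean(base_eta)))
  }
  fung <- stats::rbinom(n, 1, p_spray_i)
  insect <- ifelse(fung == 1,
                   stats::rbinom(n, 1, cfg$p_insecticide_given_spray),
                   stats::rbinom(n, 1, cfg$p_insecticide_unsprayed))

  fung_contrib_if_sprayed <- cfg$delta_fungicide +
    cfg$gamma_fung_sow * sowc + cfg$gamma_fung_lat * latc
  eta <- base_eta + fung * fung_contrib_if_sprayed
  yield <- pmax(eta + stats::rnorm(n, 0, cfg$sigma), 0.05)

  df <- data.frame(
    field_id = sprintf("F%05d", seq_len(n)),
    ted_id = sprintf("T%03d", ted_idx),
    longitude = longitude,
    yield_t_ha = yield,
    latitude = round(latitude, 4),
    sowing_doy = sowing_doy,
    maturity_group = as.character(mg_of_latitude(latitude)),
    gdd_class = as.character(gdd_class_of_latitude(latitude)),
    aridity_class = ted_aridity[ted_idx],
    pawr_class = ted_pawr[ted_idx],
    topsoil_texture = sample(field_levels()$topsoil_texture, n, replace = TRUE,
                             prob = c(0.08, 0.22, 0.3, 0.3, 0.1)),
    soil_ph = soil_ph,
    soil_om = soil_om,
    row_spacing = sample(field_levels()$row_spacing, n, replace = TRUE,
                         prob = c(0.10, 0.28, 0.12, 0.45, 0.05)),
    herbicide_program = sample(field_levels()$herbicide_program, n,
                               replace = TRUE,
                               prob = c(0.05, 0.25, 0.30, 0.40)),
    foliar_fungicide = fung,
    foliar_insecticide = insect,
    seed_trt_insecticide = stats::rbinom(n, 1, 0.60),
    seed_trt_fungicide = stats::rbinom(n, 1, 0.55),
    starter_fertilizer = stats::rbinom(n, 1, 0.33),
    lime = stats::rbinom(n, 1, 0.15),
    manure = stats::rbinom(n, 1, 0.10),
    iron_deficiency = stats::rbinom(n, 1, 0.08),
    year = sample(c(2014L, 2015L, 2016L), n, replace = TRUE,
                  prob = c(812, 960, 966) / 2738),
    stringsAsFactors = FALSE
  )

  tbl <- field_table(df, lat_range = cfg$lat_range + c(-1, 1),
                     provenance = sprintf("simulate_fields(seed=%d,n=%d)",
                                          cfg$seed, n))
  truth <- data.frame(
    field_id = df$field_id,
    expected_yield = eta,
    fungicide_contribution = fung * fung_contrib_if_sprayed,
    stringsAsFactors = FALSE
  )
  attr(truth, "coefficients") <- list(
    beta0 = cfg$beta0, lat_slope = cfg$lat_slope, sow_slope = cfg$sow_slope,
    delta_fungicide = cfg$delta_fungicide,
    gamma_fung_sow = cfg$gamma_fung_sow,
    gamma_fung_lat = cfg$gamma_fung_lat,
    ph_slope = cfg$ph_slope, om_slope = cfg$om_slope,
    lat_center = cfg$lat_center, sow_center = cfg$sow_center,
    ph_center = cfg$ph_center, om_center = cfg$om_center
  )
  list(fields = tbl, truth = truth)
}

#' Exact Shapley value of the fungicide feature under the true yield process
#'
#' For the noiseless generating process (additive main effects plus
#' fungicide-by-covariate pairwise interactions) the Shapley value of the
#' fungicide feature has a closed form under marginal background sampling
#' from the table: the main-effect term centered by the empirical spray
#' rate, plus half of each pairwise interaction deviation. This is the
#' analytic oracle against which the Monte-Carlo estimator is validated;
#' unlike the applied-treatment contribution in the ground truth it is
#' nonzero for unsprayed fields (their signed value is the penalty/benefit
#' of not spraying).
#'
#' @param truth Ground-truth data frame from [simulate_fields()].
#' @param table The matching `field_table` (defines the empirical background
#'   distribution).
#' @param field_ids Fields to evaluate (default: all).
#' @return Named numeric vector of exact Shapley values, t/ha.
#' @export
true_shapley_fungicide <- function(truth, table, field_ids = truth$field_id) {
  cf <- attr(truth, "coefficients")
  if (is.null(cf)) stop("truth lacks attached coefficients", call. = FALSE)
  idx <- match(field_ids, table$field_id)
  if (anyNA(idx)) {
    stop("unknown field id(s): ",
         paste(field_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  f_all <- table$foliar_fungicide
  sowc_all <- table$sowing_doy - cf$sow_center
  latc_all <- table$latitude - cf$lat_center
  p_bar <- mean(f_all)

  phi_interaction <- function(gamma, z_all, z_i, f_i) {
    # half of the pairwise interaction deviation, empirical moments
    0.5 * gamma * (f_i * mean(z_all) - mean(f_all * z_all) +
                     f_i * z_i - p_bar * z_i)
  }
  f_i <- f_all[idx]
  phi <- cf$delta_fungicide * (f_i - p_bar) +
    phi_interaction(cf$gamma_fung_sow, sowc_all, sowc_all[idx], f_i) +
    phi_interaction(cf$gamma_fung_lat, latc_all, latc_all[idx], f_i)
  stats::setNames(phi, field_ids)
}
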