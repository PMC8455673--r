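---
title: "Attributing a binary crop intervention: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing a binary crop intervention: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fieldshap` estimates how much a binary management intervention — foliar
fungicide application — contributed to the yield of individual soybean
fields, starting from a survey-structured table of field records. This
vignette explains the statistical machinery, the tunable parameters and their
defaults, what the synthetic data generator does and does not emulate, and
the design decisions taken where the methodology was genuinely open.

## The analysis chain

A field table holds one row per field: reported yield (t/ha at 13% moisture),
location, technology-extrapolation-domain (TED) membership and its
categorical climate/soil constructs, and 20 management and environment
predictors with no missing values. The pipeline proceeds:

1. **Exploration.** A Welch two-sample comparison of sprayed versus unsprayed
   yields (globally and within the 12 most-populous TEDs), and a linear mixed
   model of yield on fungicide use with random intercepts and fungicide
   slopes within TEDs, fitted by maximum likelihood and compared by AIC
   against the intercept-only reduction. The emphasis throughout is effect
   size, not p-values: at thousands of fields, trivial differences are
   "significant".
2. **Yield model.** An 80:20 train/test split; random search over
   `min.node.size`, `sample.fraction` and `mtry` minimizing out-of-bag MSE
   (sampling without replacement); test-set evaluation; then a refit to the
   full matrix that all interpretation stages query. Trees default to 3000
   for stability of permutation-based importance.
3. **Global interpretation.** Permutation feature importance as the ratio of
   permuted-feature MAE to original MAE (FI = 1 means "unused"), 20
   repetitions summarized by median and 5%/95% quantiles; and two-way
   partial-dependence difference curves PD(spray) − PD(no-spray) along
   sowing day and along latitude.
4. **Local interpretation.** Monte-Carlo Shapley attribution: per iteration a
   background row and a random feature ordering are drawn, and the
   prediction difference between two hybrids that differ only in the target
   feature estimates that feature's marginal contribution. The mean over
   iterations is φ (t/ha), reported with its Monte-Carlo standard error.
   φ values answer: how much of this field's deviation from the global mean
   prediction is carried by this feature?
5. **Cohorts and economics.** Four field subsets (per-TED top-20 by yield,
   global top/bottom-100, within-stratum top decile, fungicide-only versus
   co-applied with matched yield range) and a partial budget: net value
   `price × φ`, net profit `net value − chem.cost`, break-even price
   `chem.cost / φ`, with BCa bootstrap intervals on cohort mean profits.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `split_fraction` | 0.8 | — | conventional 80:20 evaluation split |
| `n_trees` | 3000 (reference profile), 300 (desk) | trees | importance stability; desk profile for iteration |
| `tuning_budget` | 20 | evaluations | OOB error surface here is a broad plateau; more adds little |
| `permutation_reps` | 20 | repetitions | enough to see the 5–95% quantile spread |
| `shapley_iterations` | 1000 | iterations/field | MC SE on φ ≈ 0.005–0.007 t/ha at this size |
| `bootstrap_reps` | 2000 | resamples | conventional for stable BCa endpoints |
| `soybean_price` | 576.30 | US$/t | early-2021 reference price |
| `chem_cost` | 61.90 | US$/ha | fungicide + application; 0 for unsprayed fields |

## The synthetic generator

The generator draws fields whose yield follows a known process: a baseline
plus a southward latitude gradient, a delayed-sowing penalty, topsoil pH and
organic-matter effects, and a fungicide term with a main effect (0.33 t/ha at
the covariate centers) that strengthens with later sowing and weakens
northward. Adoption is 30.4% marginally, with 74.8% insecticide
co-application among sprayed fields; 96 TEDs follow a power-law size
distribution solved so the largest 12 hold 61.7% of rows. Residual noise is
Gaussian with σ = 0.30 t/ha — our judgement of a realistic field-level
residual once the modeled gradients are removed.

Because the process is additive plus pairwise fungicide interactions, the
fungicide feature's exact Shapley value under empirical background sampling
has a closed form (`true_shapley_fungicide()`): the main effect centered by
the spray rate plus half of each interaction deviation. This oracle is itself
verified against brute-force subset enumeration in the test suite, and every
downstream estimator is checked against it.

What the generator does **not** emulate: spatial autocorrelation beyond the
latitude trend, weather time series, multi-year field identity, TED-varying
treatment effects (available only by post-processing in tests), or any
association between adoption and expected yield unless the `confounding`
knob is turned on. Passing tests therefore certify estimator correctness
under a known, well-behaved process — not that the real survey satisfies
these assumptions.

The latitude→GDD-class lookup is a fixed monotone banding of the 37–49°N
range chosen so all five classes occur and southerly, high-yield fields land
in the warmer classes; the published class boundaries are thermal units, so
this surrogate only preserves ordering and qualitative geography.

## Numerical and design choices

- **Welch, not pooled.** Group sizes and variances are unequal by
  construction; the df are Satterthwaite-approximated.
- **Mixed model by ML, compared by AIC**, since the compared models differ
  in random-effects structure; singular random-effect fits are tolerated and
  only optimizer failure is flagged as non-convergence.
- **Tuning objective is OOB MSE** (the forest's native regression default);
  the interpretation loss is deliberately MAE.
- **Interpretation refit uses mtry = p.** Randomized split-candidate
  subsetting is a prediction-variance device; with correlated predictors
  (here fungicide and co-applied insecticide, r ≈ 0.7) moderate `mtry` lets
  the correlate substitute at splits where the true cause is unavailable,
  which dilutes split-based credit across the pair — the familiar
  correlated-predictor importance-splitting effect. On synthetic ground
  truth this appears as fungicide φ attenuated by ~0.02–0.03 t/ha with the
  stolen share surfacing on the insecticide flag, while the OOB cost of
  `mtry = p` is negligible (< 0.5% here). The tuned `mtry` is still used for
  the predictive test-set evaluation; `pipeline_config(interpretation_mtry
  = "tuned")` restores the reused-mtry protocol.
- **PD grids** are 40 equally spaced points inside the observed co-feature
  range (no extrapolation); the smoothed curve is a lowess fit with span 0.5.
- **Shapley background** is the empirical table (one row per iteration),
  shared with a common random ordering across features so attributions
  telescope and the efficiency identity can be audited per field; per-field
  seeds derive from the master seed and the field id, so results do not
  depend on evaluation order.
- **Cohort ranking** uses reported (observed) yield — cohorts are defined
  before any model quantity — with lexicographic field-id tie-breaks. "90th
  percentile for yield" is read as the top decile (≥ P90 within stratum).
- **BCa** uses the standard bias-correction from the bootstrap
  distribution's position and jackknife acceleration; constant samples
  return a flagged point interval; the probit of the bootstrap position is
  clamped to (1/(B+1), B/(B+1)) to avoid infinite z0.
- **Degenerate inputs**: empty tables round-trip as header-only CSV; TEDs
  with fewer than 2 fields per arm are skipped with a warning; cohorts of
  one field skip the bootstrap.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full chain at the survey
size (n = 2738) but with desk-scale expensive stages: 300–500 trees, tuning
budgets of 6–20, 40-field attribution samples at 500 Monte-Carlo iterations,
and 500-replicate coverage simulations. These sizes were chosen so the whole
suite completes in a few minutes while keeping Monte-Carlo standard errors
small relative to the effects being checked.

## Known limitations

- **Model-fidelity bias.** The end-to-end attribution inherits the forest's
  approximation error. Under the default process the fitted intervention
  contrast is attenuated by 0–13% depending on the realized draw, so mean
  recovered φ can sit a few hundredths of a t/ha below the oracle even with
  the bagged interpretation refit.
- **In-sample leakage.** Following the reference workflow, attribution
  queries the model refit to the full matrix, so a field's own residual
  noise partially leaks into its attribution (error–noise correlation ≈ 0.5
  per field). Cohort means over tens of fields inherit a corresponding
  random component.
- **Marginal sampling.** Hybrid rows ignore feature dependence, so
  attributions are with respect to the marginal background distribution;
  with strongly dependent features the hybrids can be off-manifold.
- **Economics** covers a single fixed price and intervention cost; no
  discounting, quality premiums, or disease-pressure conditioning.
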