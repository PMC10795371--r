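# quollmove

Movement ecology of northern quolls (*Dasyurus hallucatus*) in an active
mining landscape: a tested, end-to-end R implementation of the analysis
pipeline for a GPS + tri-axial accelerometer study of nine collared quolls
at a Pilbara manganese mine.

## What the package does

The scientific question is how a large, active mine reshapes the movement
and energy budget of an endangered rocky-habitat specialist. The package
implements the full analysis chain, plus a synthetic-data module that
generates landscapes and habitat-selective trajectories with *known*
parameters so every stage can be validated without field data:

1. **GPS screening** (`clean_fixes`) — remove fixes with HDOP > 10, apply a
   4.5 m s⁻¹ speed ceiling (forward pass), drop capture-night windows,
   split the record into 30-min bursts and build observed movement steps
   with step lengths and turning angles.
2. **VeDBA energetics** (`compute_vedba`, `aggregate_step_vedba`) — static
   acceleration by a 10-s (two-sample) running mean per axis, dynamic
   components A = |raw − static|, and
   VeDBA = √(A_X² + A_Y² + A_Z²),
   averaged over each nocturnal 30-min observed step.
3. **Movement ranges** (`fit_kde`, `h_ad_hoc`, `isopleth`, `mcp`,
   `sample_available_ranges`, `summarize_range`) — fixed-kernel utilisation
   distributions at the 95% isopleth with the ad-hoc
   (shrink-until-fragmentation) bandwidth, 100% MCPs, buffered availability
   regions and five random circular available ranges per animal, with zonal
   habitat/TRI/distance summaries.
4. **Broad-scale selection** (`fit_zibeta_mixed`, `fit_gaussian_glmm`) —
   observed-vs-available zero-inflated beta mixed regressions for habitat
   proportions and Gaussian mixed models for continuous summaries (maximum
   likelihood, Wald CIs, random intercept per individual).
5. **Fine-scale selection, iSSF** (`fit_tentative_kernel`,
   `sample_available_steps`, `fit_clogit`, `select_models`,
   `update_kernel`, `log_rss`) — gamma/von Mises tentative kernel, five
   available steps per stratum, stratified conditional logistic regression
   maximising Π_s exp(βᵀz_obs)/Σ_j exp(βᵀz_j) by Newton–Raphson, AICc model
   selection (ΔAICc < 2), movement-kernel updating
   (k = k₀ + β_log₁₀(sl)/ln 10, κ = κ₀ + β_cos(ta)) and relative selection
   strength exp(βᵀΔz) with delta-method CIs.
6. **Energetics path models** (`step_env_covariates`, `fit_path_model`,
   `total_effect`, `relevant_range`, `fit_season_model`) — per
   environmental variable, two mixed models (step length ~ env +
   temperature; VeDBA ~ env + temperature + step length), conditional R²,
   relevant-range standardised coefficients, and the total effect
   Te = direct + indirect from partial correlations.

Everything is driveable from R, from the `stage_*()` pipeline functions, or
from a thin CLI (`run_cli()` / `inst/cli/quollmove`) with subcommands
`simulate`, `clean`, `vedba`, `ranges`, `broadscale`, `issf`, `psem`,
`report`.

## Worked example

Simulate a small study on a synthetic mine-site mosaic (true selection:
spinifex −1.0, pits −0.8, other disturbed −0.6, riparian −0.4 against the
rocky reference; TRI +0.5), clean it, and fit the iSSF:

```r
library(quollmove)
land    <- generate_landscape(seed = 1, n_rows = 200, n_cols = 200)
study   <- simulate_study(land, n_nights = 8, seed = 2)
fixes   <- degrade_gps(study$tracks, seed = 3)
cleaned <- clean_fixes(fixes, individuals = study$individuals)
cleaned
#> <quoll_cleaning>
#>   1650 fixes in; removed 47 (HDOP) + 0 (speed) + 0 (windows) + 43 (short bursts) -> 1560 kept
#>   151 bursts, 1409 observed steps

kernel    <- fit_tentative_kernel(cleaned$steps)
kernel
#> <tentative_kernel> gamma(shape 1.199, scale 96.9 m); von Mises kappa 0.201
available <- sample_available_steps(cleaned$steps, kernel, n = 5, seed = 4)
steps     <- attach_covariates(rbind(cleaned$steps, available), land)
fit       <- fit_clogit(steps, ~ habitat + tri + log10_sl + cos_ta)
fit
#> <clogit_fit> 1254 strata, K = 7, lnL = -1940.21, AICc = 3894.51
#>                     beta     se   lower   upper
#> habitatspinifex  -1.1615 0.1349 -1.4259 -0.8970
#> habitatriparian  -0.8796 0.3264 -1.5194 -0.2398
#> habitatpits      -0.8594 0.1439 -1.1415 -0.5773
#> habitatdisturbed -0.4926 0.1944 -0.8736 -0.1115
#> tri               0.3565 0.0548  0.2491  0.4640
#> log10_sl          0.5633 0.0740  0.4182  0.7084
#> cos_ta            0.1087 0.0473  0.0160  0.2013

log_rss(fit, c(habitatspinifex = 1), c())
#> # A tibble: 1 × 5
#>   log_rss    se   rss lower upper
#> 1   -1.16 0.135 0.313 0.240 0.408
```

Reading the output: all four habitat coefficients are negative — at this
(deliberately small) eight-night design the quolls already show the
injected avoidance of spinifex and mining habitats relative to rocky
habitat, and the positive TRI coefficient is selection for rugged ground.
The relative selection strength says a step ending in spinifex is about
0.31 times as likely to be chosen as an otherwise identical step ending in
rocky habitat (95% CI 0.24–0.41). At the full study design (20 nights, a
400×400-cell landscape) the estimator recovers each coefficient with
|bias| ≤ 0.05 (see the tests and `scripts/acceptance.R`).

The per-individual tracking and body-condition table for the nine field
animals ships with the package (`quoll_tracking()`), and
`summarize_individuals()` reproduces the seasonal summaries — e.g. 257 ± 10
fixes over 20.50 ± 0.50 nights per breeding-season animal, and mean
movement ranges of 6152.03 ha (breeding) vs 504.83 ha (non-breeding), a
more-than-12-fold seasonal contrast.

## Layout

- `R/` — implementation (io/config, raster dialect, synthetic data,
  cleaning, VeDBA, home range, broad models, iSSF, energetics, pipeline,
  CLI).
- `tests/testthat/` — unit, property and acceptance suites (fixtures are
  generated in code).
- `vignettes/quollmove-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical decisions and limitations.
- `scripts/acceptance.R` — see above.
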