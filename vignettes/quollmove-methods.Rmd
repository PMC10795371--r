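---
title: "Methods: movement, selection and energetics of quolls in a mining landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement, selection and energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study system and what the package models

Northern quolls are small marsupial mesopredators that den in rocky
terrain and forage nocturnally. The pipeline in this package analyses a
deployment of GPS collars (30-min fixes, 18:00–06:00 local, at most 24 per
night) with on-board tri-axial accelerometers (5-s cadence, ±4 g) and
temperature loggers, on nine animals at an active Pilbara manganese mine —
four tracked in the breeding season and five in the non-breeding season.
Three linked questions drive the design: where quolls place their movement
ranges relative to what the landscape offers (broad scale), which habitats
they choose step by step within those ranges (fine scale), and what those
choices cost energetically.

# GPS screening

Screening follows a fixed order, and the cleaning report decomposes the
removals exactly so a run is reconstructable from its log:

1. **HDOP filter.** Fixes with horizontal dilution of precision strictly
   greater than 10 are removed; a fix at exactly 10 is kept. Trial collars
   showed a mean radial error near 8 m below this threshold.
2. **Speed filter.** A single forward pass per animal from the first
   retained fix: a fix is dropped when reaching it from the last retained
   fix would imply a speed above 4.5 m s⁻¹ (the species' average maximum).
   The pass is deterministic and order-stable; a bidirectional or globally
   optimal variant would remove different fixes but the field rule names
   only the threshold, so the simplest order-stable algorithm is used and
   documented.
3. **Exclusion windows.** Half-open local-time windows `[start, end)`
   remove trap-night and post-predation fixes.
4. **Bursts.** The record splits at any gap exceeding the 30-min schedule
   plus a tolerance (default ±3 min; collar schedules drift, and 0
   reproduces the literal rule). Bursts with fewer than three locations —
   the minimum that defines a turning angle — are dropped.

Steps connect consecutive fixes within a burst. Turning angles are
counter-clockwise positive in (−π, π]; the first step of a burst has an
undefined angle and is excluded from angle fitting but retained as a step.
Timestamps are stored UTC and the night window is evaluated through a
fixed UTC+8 offset — the Pilbara has no daylight saving, so masking is
deterministic.

# VeDBA

Each axis is decomposed into a static (gravitational) part — a 10-s
running mean, i.e. the mean of two consecutive 5-s samples, with the first
sample of a segment taking its own value — and a dynamic part
A = |raw − static|. VeDBA = √(A_X² + A_Y² + A_Z²). The vector norm makes
the metric invariant to fixed collar rotation, which matters because the
circular collars rotate freely; the tests verify this invariance exactly
for static-only signals. Taking absolute values before squaring is
numerically redundant and retained deliberately for fidelity to the
published processing. Samples are assigned to steps by the half-open rule
t_start < t ≤ t_end, so a sample at a fix instant belongs to the step
ending there; samples between 06:00 and 18:00 local are discarded, and
per-step mean temperature is averaged over exactly the same masked sample
set.

# Movement ranges and availability

The utilisation distribution is a fixed bivariate Gaussian kernel density
(equal bandwidth on both axes) evaluated by fast binned convolution on a
grid padded at least 3h beyond the fixes, with cell masses normalised to
one. The movement range is the smallest set of cells reaching 95%
cumulative mass; ties in cell mass are broken in cell-index order, a
documented arbitrary rule that only matters for exactly tied cells.

The ad-hoc bandwidth starts from the bivariate normal reference
h_ref = σ̂ n^(−1/6), σ̂² = (var_x + var_y)/2, and shrinks in decrements of
0.05·h_ref, returning the smallest bandwidth whose 95% isopleth is still
one rook-connected region without interior holes; if h_ref itself
fragments, h_ref is returned. The method is named in the field literature
without parameter values; the step size, connectivity rule and hole rule
are this package's documented choices, all exposed as arguments. Grid
resolution defaults to h/4 capped at 512×512 cells — the refinement-
stability test shows halving the cell size moves the 95% area by under 2%.

Availability follows the used–available design: a 100% MCP per animal,
buffered by the radius of the largest observed movement range minus the
focal range's equal-area radius (the study's largest observed range,
8576.21 ha, has equal-area radius 5224.7 m; the field analysis works with the
rounded 5220 m), and five circular available ranges per animal, equal in
area to the observed range, centred uniformly in the buffered region.
Circles may overlap anything, including the mapped raster's edge: zonal
summaries use mapped cells only and record the unmapped fraction. Zonal
summaries are cell-centre membership tests: habitat proportions over
member cells (water stays in the denominator but is not analysed as a
selectable class), median TRI on its own 12.5-m grid, and means of the
distance layers.

The asymptote check recomputes the 95% area as fixes accumulate at
10-fix increments and declares an asymptote when the last three areas
agree pairwise within 5% — the field check names no criterion, so the 5%
band is a package choice, stated here.

# Broad-scale models

Habitat proportions are modelled with zero-inflated beta mixed
regressions: a point mass at zero whose logit-scale probability differs by
range type, and a Beta(μφ, (1−μ)φ) component with
logit(μ) = intercept + effect·observed + u_individual. Continuous
summaries use Gaussian mixed models with the same random intercept. Both
are fitted by maximum likelihood with Wald 95% CIs; effects are classified
by whether the CI crosses zero. The original analysis fitted these
structures in a Bayesian framework; maximum likelihood is this package's
single largest methodological substitution, and its validation is
parameter recovery (bias and CI coverage at the study's n = 54 ranges in 9
groups), not posterior matching. The random intercept enters the beta mean
submodel only — not the zero-inflation or precision submodels — keeping
the marginal likelihood a one-dimensional integral, which the engine
approximates by the Laplace method. Exact ones are squeezed by
y′ = (y(n−1) + 0.5)/n before fitting. Seasons are pooled, as the field
design lacks the data to model them separately.

# Integrated step selection

The tentative movement kernel fits a gamma to observed step lengths
(maximum likelihood) and a von Mises concentration to observed turning
angles with the mean fixed at zero, solving I₁(κ)/I₀(κ) = mean cos(ta);
negative mean cosines give κ = 0 and near-degenerate angle sets cap κ at
500 with a warning. Each observed step is paired with five available steps
sharing its start point: lengths from the tentative gamma, turns from the
tentative von Mises about the previous observed heading (uniform at burst
starts, mirroring the estimator's treatment of first steps).

The conditional likelihood Π_s exp(βᵀz_obs)/Σ_j exp(βᵀz_j) is maximised
by Newton–Raphson with the analytic gradient and Hessian; convergence is
max |score| < 1e−8 and the covariance is the inverse observed information.
Strata whose endpoints carry no covariate contrast contribute nothing and
are dropped with a count; strata whose observed endpoint is flagged
(off-raster or water) are dropped whole, while flagged available endpoints
are dropped individually. Complete separation raises an error naming the
covariate (|β| > 50 at any iterate, or |β| > 15 at convergence — with five
available steps per stratum the score can numerically vanish at large
finite β, so a runaway-only detector would miss textbook separation).
Candidate models (global, habitat-only, terrain-only, movement-only, null;
age × movement interactions in the non-breeding season) are ranked by
AICc with n = number of strata, and ΔAICc < 2 marks substantial support.
The supplementary table that listed the original simplified-model set is
not available, so the menu is configurable rather than guessed.

Kernel updating converts the model's log₁₀ step-length coefficient to
natural log: k = k₀ + β_log₁₀(sl)/ln 10, κ = κ₀ + β_cos(ta); the scale is
untouched because no linear step-length covariate is in the model. RSS
between two covariate vectors is exp(βᵀΔz) with a delta-method CI.

# Energetics

Per-step environment is summarised along the straight line from step
start to end, sampled at half the habitat cell size including both
endpoints — an explicit choice between along-path and endpoint-buffer
summaries, which the source description leaves open. Each environmental
variable gets a two-equation path model: step length on environment and
mean temperature; mean VeDBA on environment, temperature and step length;
both with a random intercept per individual, by maximum likelihood, on the
identical complete-case subset. Conditional R² is
(σ²_fixed + σ²_random)/(σ²_fixed + σ²_random + σ²_residual) with σ²_fixed
the variance of the fixed-effect predictor. Relevant-range coefficients
standardise each slope by the observed ranges, β·range(x)/range(y), which
makes them invariant to linear rescaling of the predictor; a total effect
Te is therefore read as the change per unit of the min–max-scaled
predictor (a Te of 0.086 reads as an 8.6% rise per unit increase — a
formatting convention, not a separate computation).

The effect decomposition uses partial correlations on pooled
observations: direct = pcor(env, VeDBA | step length), indirect =
pcor(step length, VeDBA | env), Te = direct + indirect. Whether the
original decomposition removed individual structure first is unstated;
pooling is the default and a switch residualises on individual means
first. The season model adds season (breeding = 1) as an exogenous
predictor of temperature, step length and VeDBA. Directed-separation
tests, part of the general piecewise framework but absent from the source
analysis, are not fitted by default.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated. It emulates: a 400×400-cell, 10-m habitat mosaic with class
proportions 40% spinifex, 25% rocky, 13% pits/waste dumps, 12% other
disturbed, 7% riparian, 3% water (quantile bands of a smooth Gaussian
field, ordered water–riparian–spinifex–rocky–pits–disturbed so riparian
tracks water and mining tracks rock; patch correlation length 15 cells ≈
150 m — Pilbara habitat patches are features of hundreds of metres); TRI
on its own 12.5-m grid, elevated on rocky cells so rocky has the highest
class median; exact Euclidean distance-to-rock and distance-to-disturbance
layers; and NDVI with class means matching the site's ordering (riparian
highest, pits lowest).

Movement is first-order: gamma(1.2, 120 m) step lengths (mean 144 m —
consistent with multi-thousand-hectare breeding ranges at 30-min
sampling), von Mises κ = 0.5 turns, and selection weights exp(βᵀz) over
100 candidate endpoints per step (the standard finite-candidate SSF
simulation; its small bias is accepted and measured). Defaults inject
avoidance of spinifex (−1.0), pits (−0.8), other disturbed (−0.6) and
riparian (−0.4) against rocky, and TRI selection (+0.5). Animals sit at a
rocky den by day, start each night there with a uniform heading, and a
wall of off-raster candidates forces a free turn after five failed
redraws. Activity per epoch is realised step length over the kernel mean;
the accelerometer adds a dynamic component of SD 0.35 g per unit activity
to a slowly rotating gravity projection, so the true VeDBA–habitat effect
arises only through β-driven habitat occupancy — giving the energetics
stage a recoverable ground truth. GPS degradation applies isotropic
Gaussian error (8.3 m per axis, the trial-collar figure), 5% fix failure,
and an HDOP mixture with 3% mass above 10.

What the generator does **not** emulate: terrain-driven movement costs,
home-range drift, den switching, behavioural states, conspecifics and
predators, temperature-dependent activity (temperature follows a pure
diel sinusoid), and autocorrelated GPS error. Passing tests therefore
demonstrate that the estimators recover the parameters of this generative
model at the study's design size — not that real quoll data satisfy these
assumptions.

## Measurement error and estimator validation

With 8.3 m positional error on 10-m habitat cells, endpoint covariates are
misclassified near patch edges, and the conditional-logistic estimator —
like any SSF estimator fed error-contaminated covariates — attenuates
strong habitat coefficients by roughly 0.13–0.15 with Wald coverage
falling to 0.5–0.7 (measured at 30 replicates of the full design). The
estimator-recovery suite therefore validates the estimator on true
positions (fix failure and HDOP degradation retained, so screening still
does real work): there each coefficient's bias is under 0.05 and coverage
sits in 0.90–0.97 over 100 replicates. A separate test keeps the
full-noise pipeline honest by requiring correct recovery of all
coefficient signs. Attenuation under positional noise is a property of
the design worth knowing about when interpreting the field estimates.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty fix files are identities;
an all-zero proportion response returns a singular-fit report rather than
a crash; collinear MCPs warn with zero area; fully unmapped circles return
NA summaries with a warning. Tie-breaks (isopleth cell order), edge rules
(static[0] = raw[0]; half-open raster cells with shared edges belonging to
the cell right/below; (t_start, t_end] sample membership) and tolerances
(score < 1e−8; burst tolerance ±3 min; asymptote 5%) are all stated at
their definitions.

Test problem sizes are chosen to bound the full suite at a few minutes of
CPU: the estimator-recovery suite runs 100 replicates of the full study
design (≈3,100 strata each) on one shared 400×400 landscape; the
mixed-model recovery suite runs 200 replicates at the study's n = 54;
distributional checks use 2,000–20,000 draws with tolerances stated next
to each assertion. The acceptance script replicates the full study five
times and reports recovery bias.

# Known limitations

- GeoTIFF input is not read; rasters use the package's documented ASCII
  dialect (no GDAL-backed reader is a dependency).
- Mixed-effects (random-slope) step selection is out of scope, as in the
  source design; the iSSF pools individuals by season.
- The zero-inflated beta integral uses a Laplace approximation; with nine
  groups and moderate variances this is adequate for recovery but is not
  an exact likelihood.
- Partial-correlation effect decomposition ignores grouping by default;
  the residualising switch is provided but is not the primary output.
- The speed filter is one forward pass; fixes after a long gap are judged
  against the last retained fix, not re-evaluated globally.
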