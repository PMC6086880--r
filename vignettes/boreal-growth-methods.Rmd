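---
title: "Modelling boreal tree growth responses to climate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling boreal tree growth responses to climate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`borealgrowth` estimates how the radial growth of boreal tree species
responds to temperature and water availability across a spatial climate
gradient, and projects stand-level growth under warming scenarios by
space-for-time substitution. This vignette documents the model, the
numerical and design choices, and what the synthetic-data validation does
and does not demonstrate.

## From rings to observations

Each cored tree contributes one observation. Dated ring widths are
converted to annual basal area increments (BAI) outside-in: the radius at
the end of the outermost ring year is DBH/2 and each earlier radius is
obtained by subtracting that year's width, so
`BAI_t = pi * (r_t^2 - r_{t-1}^2)`. This telescopes exactly: the series
sum equals the outer disc minus the pith disc, which the test suite
asserts to 1e-9 relative across random series. DBH is treated as the
reconstruction's outer value without a bark-thickness correction — bark
is outside scope and the synthetic generator uses the same convention, so
the round-trip is exact.

Outlier rings (anomalous detections) are screened per tree with Tukey's
rule at k = 3 on the annual growth values, using type-7 (linearly
interpolated) quartiles. The quartile convention matters at these small
n; it is fixed and the brute-force oracle in the tests uses the same
rule. Screening is applied within the growth window by default
(`screen = "series"` is available): the window is what enters the model,
so fences estimated from the same years are the least biased by ontogeny.

The growth window is the most recent at-most-15 calendar years
intersected with 1985–2005; trees with fewer than 10 eligible years are
dropped (a logged outcome, not an error). BAI, reconstructed annual
diameter ("size") and ring-count age are averaged over the window.

## Climate variables

Monthly PET follows the FAO-56 Penman–Monteith reference formulation with
monthly-mean daily inputs: vapour pressure from dewpoint, pressure from
altitude, extraterrestrial radiation at the mid-month day of year, soil
heat flux zero, and measured solar radiation with the clear-sky ratio
bounded to [0.3, 1]. Wind speed is not available from the station inputs
and defaults to the FAO-56 standard 2 m s⁻¹ (configurable). Daily
reference ET is floored at zero and scaled by days-in-month. The test
suite compares this implementation against an independently transcribed
FAO-56 oracle over a 1000-point input sweep at 0.1 mm.

The climate moisture index is the exact balance `CMI = Prec - PET`, with
no smoothing or capping, summed over May–September (CMI_GS) or
June–August (CMI_SUMMER). Snowfall is the January–March total, classed
low (< 140 mm), medium (140–200 mm, both bounds closed), high (> 200 mm).
Annual summaries are averaged arithmetically over each tree's window
years.

## The growth model

Per species, with Gaussian errors on the log scale:

```
log(BAI + 1) = beta + log(Size) + Size
             + f(Age) + f(BAL) + f(BA) + f(Slope)
             + f(T) + f(CMI) + f(T, CMI)
             + soil + snow + stage (+ factor-modified smooths) + eps
```

Design choices, and why:

* **Basis bounds.** "Smoothness bounded to four" is read as the basis
  dimension (`k = 4`) of each cubic regression spline, the standard
  reading for penalized spline models; the tensor-product interaction is
  bounded to 3 per margin. The tests assert that no fitted smooth's
  effective degrees of freedom exceed its bound.
* **Factor modifiers.** The categorical error terms "associated with the
  origin of the model and the smooth functions" are implemented as
  parametric intercept offsets plus ordered-factor difference smooths
  (`s(x, by = factor)` with the main smooth retained): soil modifies the
  temperature and CMI smooths, snow the CMI smooth, stage the
  temperature, CMI, BA and BAL smooths. This is the closest standard
  mgcv construction and is flagged as an interpretation.
* **Soil taxonomy.** Eight field categories (six mineral drainage ×
  texture classes, shallow/stony, hydric) must collapse to a seven-level
  factor; which pair merges is genuinely open. The default merges
  shallow/stony with hydric into one level — both are thin-rooting-volume
  environments — and the mapping is configuration, not hard-coded.
* **Smoothness selection.** REML by default (configurable); the default
  engine is the exact `mgcv::gam` fit up to 10,000 observations. The
  discrete `bam` approximation is available for larger data but is not
  the default: during development its covariate discretization visibly
  biased the fitted temperature optimum relative to the exact fit, so
  exactness is preferred wherever feasible.
* **Smearing.** Duan's factor `S = mean(exp(residuals))` is computed
  globally by default (`smear_by` enables per-stratum factors; the choice
  is open in principle and global is the simpler estimator). The
  back-transform is `exp(eta) * S - 1`; `S = 1` exactly for zero
  residuals and converges to `exp(sigma^2 / 2)` for Normal residuals.
* **RMSE normalization.** RMSE is reported on the log-response scale as a
  percentage of the training log-response range. A relative error needs a
  denominator and the response range is the natural scale-free choice;
  this is asserted as a package decision.
* **Degenerate inputs.** Single-level factors and near-constant
  covariates are dropped from the formula with a recorded downgrade; a
  perfectly constant response falls back to an explicit intercept-only
  fit (penalized selection is undefined at zero scale). Factor levels
  unseen in training fold to the reference level with a warning at
  prediction time.
* **Climate-variable selection** fits the four combinations of
  {T_MAX, T_MEAN} × {CMI_GS, CMI_SUMMER} and takes the AIC minimum, with
  ties broken deterministically in declared order. Age is retained in all
  models to absorb the sampling bias of tree-ring collections (old
  fast-growers and young slow-growers are under-sampled).

## Scenario projection

Scenarios combine a nominal T_MAX increase (1–4 °C), a nominal
growing-season precipitation change (−5, 0, +5, +15 %) and a linear PET
coupling of 43.25 mm °C⁻¹ (so 1–4 °C maps to 43–173 mm of added PET).
Changes vary locally: warming is amplified toward the high-latitude edge
and precipitation increases toward the east edge, as linear ramps
normalized to an exact area-mean of 1, so the area-mean applied change
equals the nominal scenario.

Each inventory stem class (2-cm DBH bins above 9 cm, half-open
left-closed, per-hectare expansion factors from its source subplot) is
point-predicted with size = class midpoint, age = stand mean age, BAL
from the class table (strictly larger classes), and plot covariates; no
growth feedback on DBH is simulated (single-step projection). Plot growth
per hectare is aggregated as an unweighted mean over 15-km grid cells —
"growth was averaged per polygon" without weights, and unweighted means
are the default (a weighted variant would require a stem-count rationale
the data do not force). Zone summaries report the mean polygon change ±
SE, the fraction of polygons declining, and N. A climate-space guard
reports, per species, the count-weighted fraction of stems whose
perturbed T_MAX stays within the temperature range observed during
fitting.

The planar km grid replaces a geographic CRS throughout; a "15-km
polygon" is a 15 × 15 km cell. Nothing in the aggregation contract needs
geodesy.

## The synthetic landscape and ground truth

The generator emulates the study conditions: mean annual temperature
spans about −4.7 to 6.7 °C along the latitude-like axis and annual
precipitation about 700–1600 mm along the longitude-like axis; a
July-peaking seasonal cycle, summer-weighted precipitation, winter
snowfall (median January–March total near 160 mm, straddling the three
snow classes), solar radiation and dewpoint consistent with a cold
continental climate; plots with slope classes (median 9 %), a seven-level
soil mix, log-normal stand ages, and nested stem tables calibrated to a
median plot basal area near 26–29 m² ha⁻¹.

Three structural choices deserve note:

* The growing-season share of precipitation declines toward the north,
  offsetting the latitudinal PET gradient so that CMI_GS is nearly
  orthogonal to T_MAX (R² < 0.01 on the default grid) — matching the weak
  coupling of the two axes in the study region and making the tensor
  interaction identifiable.
* Per-cell continentality (diurnal half-range) and shoulder-month
  precipitation share vary randomly, so T_MAX is not an affine function
  of T_MEAN and CMI_GS is not an affine function of CMI_SUMMER; without
  this, AIC selection among the four candidates would be undefined.
* The truth surface is a product of a saturating size term, a
  negative-exponential age decline, negative-exponential competition
  terms, a Gaussian temperature bump, a broad Gaussian (or linear, or
  flat) moisture response, a mild slope penalty and categorical
  multipliers; noise is log-normal on the log(BAI + 1) scale, matching
  the model's error assumption. Growth is strictly positive and unimodal
  in temperature, which makes threshold recovery a meaningful test.

Ring widths are back-computed so each window-year BAI equals the truth
expectation times the log-normal noise; pre-window years share the
remaining radius equally down to the pith, so ring counts equal age
exactly. The expected BAI is evaluated at the measured DBH and the
window-mean ring age — both exactly recoverable downstream — so the
zero-noise round-trip is exact to numerical tolerance. The window-mean
reconstructed diameter is slightly below the measured DBH; this known
covariate attenuation affects the size term only, not the climate
responses the package is designed to recover.

Residual noise magnitude is not known for real growth; `sigma_log`
defaults to 0.3 as a plausible working value and is configuration, not a
claim.

**Study-condition truths.** The threshold-recovery simulations use a
truth optimum of 8.0 °C (near the warm end of the sampled gradient, like
the thresholds the model class is meant to detect) at n = 5000 trees and
sigma = 0.3; across 10 replicate seeds the fitted partial-effect argmax
lands within ±0.5 °C of the truth in at least 9. The scenario-projection simulations
use an optimum of 5.0 °C — the midpoint of the synthetic boreal T_MAX
span (~0–7.5 °C) — so that the zone contains sites on both sides of the
optimum; under the default scenario grid, zone-mean growth rises at +1
and +2 °C and shrinks or reverses at +4 °C at every precipitation level,
the transitory-benefit pattern.

**What passing tests do not show.** The generator has smooth gradients
plus independent cell-level noise but no spatially autocorrelated
residual fields, no disturbance (fire, budworm), no mortality,
recruitment or composition change, no species migration, and no
interannual climate variability (normals only). Recovery on this
landscape demonstrates that the estimator chain is correct and unbiased
under its own assumptions; it does not validate those assumptions against
real forests, and projections inherit the single-step, mean-climate
limitations of the space-for-time design.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 5000-tree simulations
(1250 plots × 4 cored trees) for recovery and validation, 400-plot
inventories for the scenario grid, 20 replicates for selection power and
10 for threshold recovery — sizes at which the Monte-Carlo error of each
check is well below its assertion margin. Every stage takes an explicit
seed; identical seeds give byte-identical artifacts, which the pipeline
tests assert on the CSV outputs.
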