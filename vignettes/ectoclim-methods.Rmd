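---
title: "ectoclim: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ectoclim: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ectoclim` estimates how climate scenarios affect a small diurnal
ectotherm through the mechanisms the animal actually experiences, and
feeds those mechanistic quantities into correlative distribution
ensembles. This vignette documents the models stage by stage: what each
assumes, which parameters matter, and where the design was genuinely open.

## 1. The synthetic world

`generate_monthly_climate()` builds monthly normals from a deliberately
minimal parametric surface: an annual-mean plane in latitude
(default −0.6 °C per degree of absolute latitude around a 28 °C
equatorial reference), sinusoidal seasonality whose half-amplitude grows
with |latitude| (2 °C + 0.35 °C/°), a fixed 10 °C diurnal range, and a
summer-wet precipitation cycle (80 mm/month base, relative amplitude 0.5).
Cell-level Gaussian noise perturbs the annual mean; precipitation noise is
multiplicative log-normal. This reproduces the one contrast the analysis
needs — a temperate-to-tropical gradient in both mean and seasonality —
and nothing else.

What it does *not* emulate: spatial autocorrelation of weather anomalies
(noise is independent per cell), realistic topography (elevation defaults
to sea level, with an optional −6.5 °C/km lapse), interannual variability,
or precipitation-temperature covariance. Passing tests on this world
therefore demonstrate that the pipeline machinery is correct and
internally consistent, not that any particular real species is vulnerable.

Warming scenarios are additive temperature offsets (scalar, monthly or per
cell) with a multiplicative precipitation factor — the standard
anomaly-application shape. Multi-model projections are combined by
`average_projections()` with equal weights; the conventional ensemble mean
is used because no defensible basis exists for unequal model weights at
this level of abstraction.

The reference virtual species couples a Gaussian response in annual mean
temperature (bio1) with a decreasing logistic response in maximum water
loss, combined multiplicatively. Both responses are deliberately narrow
(breadth 1/14, logistic scale 1/25 of the predictor range): the species is
meant to carry a strong, recoverable niche signal so that
distribution-model recovery measures the modelling chain rather than the
intrinsic ambiguity of a generalist's presence data. Occurrences are drawn
with probability proportional to suitability and jittered uniformly within
the cell, which keeps 10 arc-minute thinning meaningful.

## 2. Microclimate

One representative day (the 15th) is simulated per month, 24 h each, and
annual aggregates weight each day by its month length — 288 simulated
hours per cell-year. This mirrors the monthly-normal design of global
microclimate models and keeps grid-scale cost trivial.

*Diurnal air temperature.* The day branch is a half-sine from tmin at the
(rounded) sunrise hour to tmax one hour after solar noon; the night branch
decays exponentially back to tmin at the next sunrise. The night decay
constant defaults to 0.04 h⁻¹, i.e. near-linear nocturnal cooling. That
value was chosen so the daily mean of the interpolated series stays within
a few hundredths of a degree of (tmax + tmin)/2 at any latitude — the
property monthly normals implicitly assume; faster decay constants bias
the annual mean cold by 1–2 °C. During polar night the series is flat at
the midpoint.

*Soil.* Temperatures follow the classic conduction solution: annual and
diurnal sinusoids damped by exp(−z/d) with phase lag z/d, around the
annual mean. Damping depths default to 0.10 m (diurnal) and 1.9 m
(annual), typical of moist mineral soil. The annual wave's phase is
anchored so the surface daily mean matches the current representative
day — this keeps the standalone function consistent with the monthly
series that drives it.

*Radiation, humidity, wind.* Solar flux is clear-sky beam
(1361 W m⁻² × transmissivity 0.7) scaled by the zenith cosine and zero
below the horizon. The ground surface runs above air temperature by
0.015 °C per W m⁻² of solar flux — a dry-surface energy-balance proxy
giving midday excesses of 10–15 °C. Sky radiant temperature sits below
air temperature by a 20 °C clear-sky offset shrunk under humid skies.
Relative humidity is a saturating function of monthly precipitation,
rh = 20 + 75·(1 − e^(−P/60 mm)) percent: the minimal monotone coupling
that lets water-loss outputs respond to precipitation scenarios. Wind is
1 m s⁻¹ at the 1.2 m reference height, reduced to animal height along a
log profile with 4 mm roughness (short-grass habitat). All heights,
depths, offsets and scales are `microclimate_config()` settings.

Local solar time is used throughout; there is no snow, soil moisture,
terrain shading or cloud time series.

## 3. The ectotherm heat and water budget

Operative temperature T_e is the root of the steady-state balance of
absorbed shortwave, absorbed and emitted longwave, and convection, per
unit total area. The animal is a cylinder of length:diameter 6:1 at
tissue density 1000 kg m⁻³; 40% of total area intercepts beam solar;
sky and ground view factors are 0.5 each; absorptance 0.85, emissivity
0.95. Convection uses h = 0.6 (k/D) Re^0.5 with a 5 W m⁻² K⁻¹
free-convection floor. The left side of the balance is strictly
decreasing in T_e, so the root is unique; a damped Newton iteration from
T_air converges to |ΔT_e| < 10⁻⁶ °C, and the residual is attached to
every simulated series so tests can assert it. In the shaded posture
direct solar is zero and the radiant surroundings are at local air
temperature, which collapses T_e to T_air exactly.

Body temperature is taken equal to operative temperature: at < 10 g the
thermal time constant is minutes, well below the hourly resolution, so
transient heating is ignored.

Behaviour is a memoryless hourly cascade: night → retreat; open-habitat
T_e within the 25–75% field body-temperature quantiles (vt_min, vt_max) →
active; below the band but at or above the 17 °C emergence temperature →
basking; otherwise → burrowed at the depth (grid
0.025–1 m) whose soil temperature is nearest the preferred temperature,
ties to the shallower depth, body temperature clamped to [CTmin, CTmax].
Basking hours are *not* counted as activity: activity is defined by the
quantile band. The thermal safety margin uses the full-sun operative
temperature — TSM = CTmax − max(T_e,open) over all hours of the year —
because the safety margin is meant to measure exposure of an animal denied
behavioural escape; the behaviourally chosen microhabitat enters the
activity, metabolism and water-loss outputs instead.

Metabolism is VO₂ = a·m^b·e^(qT) (ml O₂ h⁻¹); the default coefficients
(a = 0.1, b = 0.8, q = 0.07) are documented assumptions in the
conventional range for small lacertids, exposed as traits. Water loss sums
three components: cutaneous (vapour-density gradient across skin plus
boundary-layer resistance, defaults 12 000 and 300 s m⁻¹, sized to give
resting losses near 0.01–0.02 g h⁻¹ for a 5 g animal), respiratory
(ventilation = VO₂ / (0.2094 × extraction efficiency 0.16), exhaled air
saturated at body temperature), and ocular (free-surface evaporation from
0.2% of skin area, eyes open only when active or basking). Gradients are
floored at zero; retreat air is assumed near-saturated (95% rh) at the
burrow temperature.

## 4. Embryonic development

The development-rate model is linear (degree-day): rate 1/days regressed
on temperature over the temperatures whose hatching success reaches the
threshold (default 0.5), giving the developmental zero t₀ = −c/s and the
thermal constant 1/s. A linear rate is the minimal model identifiable
from period-and-success tables and is replaceable behind the
`dev_rate_model` interface. Viable bounds are the lowest and highest
tested temperatures meeting the success threshold, each extended outward
by half the spacing to the adjacent tested temperature.

Hourly development increments are max(0, T − t₀)/(24·DD), zeroed outside
the viable bounds: development *arrests* rather than fails outside the
bounds — lethality would require data the tables do not contain. The nest
sits at 0.05 m soil depth; oviposition is the first representative day
whose daily mean nest temperature reaches the lower viable bound.
Incubation is the elapsed days until cumulative development reaches 1,
wrapping cyclically; if hatching is not reached within 365 days the
per-cell layer records a censored value of 365 days (the bare
`incubation_period()` returns `NA`), which keeps the predictor defined
across the whole grid instead of silently shrinking the modelling domain.
The "time window" is the month-length-weighted count of hours with nest
temperature inside the viable bounds.

## 5. Hybrid distribution ensembles

The predictor stack holds bio1, bio5, bio6, bio12, bio18 (bio18 by
exhaustive scan of the 12 cyclic quarters, ties to the earliest) plus the
biophysical layers. Presences are collapsed to one record per cell;
pseudo-absences are uniform random cells from the valid mask excluding
presence cells, 10 × the presences by default. Spatial thinning is greedy
randomized: random visiting orders with the deterministic input order as
the first pass, best retained set over 20 restarts, great-circle distances
in arc-minutes.

Five learner families fill the conventional algorithm slots: binomial GLM
with quadratic terms; gradient-boosted trees (100 rounds, depth 3,
learning rate 0.1); a MaxEnt-style exponential-family model implemented as
ridge-regularized logistic regression on linear + quadratic features;
probability random forest (300 trees); and an RBF soft-margin SVM with
probability calibration. All emit scores in [0, 1]. The evaluation and
ensembling logic — random stratified 70/30 splits, five replicates, AUC
(tie-aware rank form) and max-TSS on the held-out 30%, discarding members
with TSS ≤ 0.6, TSS-proportional weights — is independent of any one
learner, which is the point: the procedure, not the learner, is the
method. Predictors are standardized to each training split's mean and
variance. The ensemble's binarization threshold maximizes TSS on the
pooled out-of-sample scores of surviving members, ties to the smaller
threshold; replicates are pooled rather than thresholded per model because
the pooled threshold is the one applied to a single ensemble map. Range
change uses latitude-corrected cell areas (∝ cos lat).

## 6. Attribution

Per-variable contributions use the mean-anchored response curve: for
variable v, the masked-mean change Δv̄ between future and current stacks
is pushed through R_v (ensemble suitability along v with all other
predictors at current masked means), and the contribution is
R_v(v̄ + Δv̄) − R_v(v̄), classed increased/unchanged/decreased at ±0.01
suitability units. Importance is permutation AUC-drop, averaged over
repeats and ensemble members with ensemble weights and floored at zero —
a transparent, learner-agnostic substitute for package-specific importance
metrics, and the one documented deviation from common SDM-package
defaults. Contribution and importance are reported side by side; they
answer different questions (directional effect of the projected shift
versus overall reliance of the fit).

## 7. Numerical choices and degenerate inputs

* Newton iterations stop at |ΔT_e| < 10⁻⁶ °C (max 100 iterations); the
  returned residual lets callers verify convergence.
* Quantiles use the linear-interpolation definition (type 7).
* Ties: retreat depth → shallower; max-TSS threshold → smaller; warmest
  quarter → earliest start month.
* Zero-cell extents, inverted tmax/tmin, negative precipitation factors,
  all-zero suitability, empty score lists, empty soil profiles and
  unknown config keys are rejected with messages naming the offending
  field. Empty occurrence sets thin to empty sets (not an error).
* Seeds are explicit arguments everywhere; no function reads or leaves
  global RNG state that matters across calls.

## 8. Problem sizes

The test suite and the acceptance script run the full chain at desk
scale: 20 × 20 to 40 × 40 cell worlds, 288 simulated hours per cell-year,
200 occurrence records, five learners × five replicates, ten recovery
seeds. These sizes were chosen as the smallest at which every statistical
property being asserted (recovery correlations, AUC, noise scales) is
stable; all of them scale linearly in cells and records.

## 9. Known limitations

Single open-habitat configuration (one shade level, configurable retreat);
no energy or hydration budget feeding back on behaviour; no dispersal or
biotic interactions in the SDM stage; random rather than spatially blocked
cross-validation; degree-day (not curvilinear) development kinetics; and
the synthetic world's independence assumptions listed in section 1.
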