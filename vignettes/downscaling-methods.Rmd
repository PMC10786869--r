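---
title: "Methods: detrended quantile mapping for marine climate downscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detrended quantile mapping for marine climate downscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marindown)
```

## Overview

`marindown` turns coarse, biased ocean fields from global climate models
into fine-resolution regional projections: per member, a detrended
quantile-mapping (DQM) bias correction at the model's working resolution,
then a statistical downscaling step onto the grid of a high-resolution
historical reference, then equal-weight ensemble statistics, skill scores
and a three-source uncertainty analysis. This vignette records the method,
its assumptions, and the numerical and design choices, so that a user can
judge what a passing test suite does — and does not — demonstrate.

## The DQM model and its assumptions

For one cell and one calendar month, let $x_{mh}(t)$ be the model historical
series and $x_{rh}(t)$ the reference historical series over the training
window. Training (`fit_dqm`):

1. **Scaling.** In additive mode $s = \overline{x_{rh}} - \overline{x_{mh}}$;
   in multiplicative mode $s = \overline{x_{rh}} / \overline{x_{mh}}$. After
   scaling, the historical means agree exactly.
2. **Detrending.** Both series are detrended with an ordinary-least-squares
   linear trend in fractional years. Detrending is *mean-preserving*: the
   fitted line is removed around the series mean, so the detrended sample
   keeps its level.
3. **Adjustment factors.** At $n$ equally spaced probabilities
   $p_i = (i - \tfrac12)/n$, the adjustment is the difference (additive) or
   ratio (multiplicative) between the detrended reference and detrended
   model empirical quantiles.

Application (`predict`/`apply_dqm`): scale the projection, fit and remove
its *own* linear trend — anchored at the training-period level, so that a
projection value is corrected at the probability of its detrended anomaly
within the *trained historical* distribution — look up the adjustment by
linear interpolation between the trained model quantiles (constant beyond
the outermost quantiles), and re-add the projection's trend. Because the
trend is removed before mapping and restored afterwards, the model's climate
trend passes through the correction unchanged: exactly so on noiseless
input, and within a few percent on noisy monthly series.

Assumptions worth keeping in mind:

* **The bias is stationary.** The transform learned over the historical
  window is applied unchanged to 2100. This is the standard, untestable
  assumption of all empirical bias correction.
* **Trends are locally linear.** DQM removes a *linear* trend. A
  scenario-driven trajectory is piecewise-linear (historical rate, then the
  scenario rate), so the gridded drivers apply each transform separately to
  the historical segment and to the projection segment, each detrended by
  its own line. One line over a 108-year kinked trajectory would leave
  curvature in the detrended values and push the historical part of the
  series into the adjustment tails; segmenting removes that artefact while
  leaving `apply_dqm` itself a plain single-series operation.
* **Months are exchangeable within a window.** Per-calendar-month fitting
  (12 transforms per cell, the default) prevents the seasonal cycle from
  being confounded with the bias; it costs sample size (one value per year
  per month), which the quantile interpolation tolerates.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_quantiles` | 100 | – | conventional; probabilities $(i-\tfrac12)/100$ keep the tails away from 0/1 |
| `mode` | additive (T, S, pH); multiplicative (O2, chl) | – | ratio correction cannot produce negative concentrations; `clamp_zero` additionally floors additive corrections of positive variables |
| `per_month` | `TRUE` | – | seasonal-cycle/bias separation (above) |
| `training_window` | full model/reference overlap | years | the reference's span is the binding constraint |
| IDW `n_neighbors`, `power` | 8, 2 | – | inverse-square weighting over the eight nearest valid points |
| match `h_tol`, `v_tol` | 100, 1 | m | deliberately literal point-matching tolerances; 100 m is far tighter than the grid spacing, so only essentially co-located records pair |
| `window` (internal variability) | 21 | years | a centred 21-year running mean separates decadal variability from the forced trend |

## Numerical choices

* **Quantile estimator**: linear interpolation between order statistics
  (type 7, the default of mainstream numerics stacks), both in training and
  in the ensemble percentiles; ties collapse by averaging adjustments over
  duplicate model quantiles.
* **Beyond the trained tails** the adjustment is constant (the boundary
  quantile's adjustment) — a bounded extrapolation that cannot invert order.
  The mapping is monotone non-decreasing by construction.
* **Trend fitting** is closed-form OLS on fractional years at mid-month; at
  least two distinct time points are required, 24+ months recommended.
  Series too short to detrend (degenerate corners of split data) are
  corrected with a zero-slope trend at the training level.
* **Regridding** is bilinear inside the source-node hull with weights
  renormalised over valid corners; a target node with all four corners
  missing stays missing and is then filled by IDW extrapolation
  (great-circle distances on a 6371-km sphere). Coarsening is the unweighted
  block mean of non-missing children: at ≤0.5° over a regional domain the
  cos(latitude) variation within a block is negligible (a documented
  limitation, as is the equal-weight treatment of cells in the spatial
  skill metrics; cos-latitude weighting is available via `weight_lat`).
* **Temperature skill is computed in Kelvin** (Celsius inputs are shifted by
  273.15 before the ratios are formed): the mean ratio α is unstable and can
  change sign near 0 °C.
* **Ensemble spread** uses the population (divide-by-N) standard deviation
  so a single member yields 0 rather than `NA`; percentiles 2.5/50/97.5 use
  the same order-statistic interpolation as the quantile mapping. A
  cell/time missing in any member is missing in every statistic.
* **Internal variability** uses annual means of calendar years with all 12
  months present; the running mean is computed only where the full window
  fits (the first and last 10 years drop out), so a purely linear trend
  yields exactly zero rather than spurious edge residuals.
* **Longitudes** are normalised to [−180, 180); domains crossing the
  antimeridian are out of scope.

## Decisions where the method description was genuinely open

* **Resolution matching direction**: the coarse corrected field is brought
  *up* to the fine grid before per-fine-cell DQM. The alternative (degrading
  the reference) would discard exactly the sub-grid variability the
  downscaling is meant to transfer.
* **Step-5 quantile lookup** uses the *trained historical* model quantiles
  (standard DQM), not quantiles re-estimated from the projection window.
* **Scenario vs model uncertainty**: scenario uncertainty is the min–max
  range of per-scenario *ensemble-mean* changes; model uncertainty the
  min–max range of *per-member* changes under one scenario; internal
  variability is estimated from that scenario's ensemble mean only.
* **Observation matching** ignores time stamps: records pool into one
  distribution per cell and are compared against the cell's climatological
  distribution — a deliberately seasonality-agnostic distributional check.
* **Ensemble weighting**: every realization carries equal weight;
  down-weighting dependent realizations of one model is explicitly left out.

## The synthetic study setup

The generators (`synth_config`, `make_reference`, `make_member`,
`make_observations`, `make_ensemble_suite`) emulate the structure of the
real problem at desk scale, with every distortion known:

* fine 24×24 grid at nominal 1/12°, coarsening factor 6 (coarse 4×4 at
  0.5°), mirroring the resolution ratio between a global model and a
  high-resolution reanalysis;
* monthly series 1993–2100 with the historical window ending in 2014;
* value = smooth large-scale pattern + stationary fine-scale pattern +
  seasonal sinusoid + piecewise linear trend + AR(1) monthly noise
  (coefficient 0.6, marginal σ = 0.5), so quantile corrections face
  realistic autocorrelation rather than white noise;
* members carry a known additive bias map, a variance inflation factor, and
  per-scenario trends of 0.1 / 0.2 / 0.4 units per decade after 2014 —
  warming rates of 1, 2 and 4 units per century spanning low- to
  high-emission pathways;
* a connected coastal land blob (10 % of cells) exercises the masking and
  IDW paths; observations are drawn at grid nodes with Gaussian noise, with
  an optional jittered fraction placed beyond the matching tolerance.

What the synthetic world does **not** contain: spatially correlated noise,
non-stationary biases, cross-variable physical consistency, mesoscale
dynamics, or tripolar/curvilinear native model grids. Passing tests
therefore demonstrate that the *machinery* recovers known truth under the
stated statistical assumptions — not that those assumptions hold for any
particular real model–reference pair.

## Problem sizes used by the test suite

Unit tests run on 2×2 to 12×12 domains with a few years of monthly data.
The end-to-end check runs the full study shape — 2 models × 2 realizations
× 3 scenarios on the 24×24/4×4 grids over 1993–2100 — which completes in a
few minutes on a single core; truth-recovery checks (bias removal, trend
preservation, scenario-range recovery) use the generator defaults with fixed
seeds and tolerances derived from the injected noise model (slice-mean
variance of AR(1) noise propagated through the ensemble and range
operations).

## Known limitations

* Univariate correction only: joint temperature–salinity (or other
  multivariate) consistency is not enforced.
* Unweighted spatial means in basin series and (by default) skill metrics.
* No conservative remapping; bilinear + IDW is adequate for smooth fields
  but not for flux-conserving applications.
* The 100 m observation-matching radius is literal; with an ~8 km grid it
  accepts only records essentially on a node. Widen `h_tol` for realistic
  match rates with scattered observations.
* Calendars are collapsed to a uniform monthly index; sub-monthly data are
  out of scope.
```{r session, echo = FALSE}
sessionInfo()$R.version$version.string
```
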