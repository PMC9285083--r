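---
title: "Methods: detecting drought priming in crop yields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting drought priming in crop yields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`primecrop` quantifies a stress-memory ("priming") effect: whether a mild
early-season drought reduces the yield loss a maize or soybean crop suffers
from a later drought during reproductive development. This vignette is the
package's account of the models it implements, the choices that were
genuinely open, and what the synthetic experiments do and do not show.

## The detection chain

### Vegetation index and smoothing

Canopy development is tracked with the wide dynamic range vegetation index,
`(alpha * NIR - red) / (alpha * NIR + red)` with `alpha = 0.1`, which stays
nearly linear at the high leaf-area values maize reaches in midsummer.
Only composites with a good quality flag enter; flagged composites are
retained in the tables (never silently dropped) so filtering decisions stay
visible. The 8-day composites are interpolated to a daily grid with
`stats::smooth.spline`, smoothness chosen by generalized cross-validation
per pixel-year. A pixel-year must offer at least 8 good composites spanning
at least 120 days with no gap wider than 32 days; anything less is excluded
and counted in the run report rather than imputed.

### Shape-model registration

A crop-specific reference curve `h(x)` (built by averaging smoothed daily
series over calibration years, with fixed reference stage dates: maize
150/200/240/265, soybean 170/225/240/270) is registered onto each observed
daily series by minimizing the RMSE of `yscale * h(xscale * x + tshift)`
with the Levenberg-Marquardt algorithm (`minpack.lm::nls.lm`).
Numerical choices:

* initialization `(1, 0, 1)`; box bounds `xscale` in [0.6, 1.6], `tshift`
  in [-60, 60], `yscale` in [0.3, 2.0]. The bounds keep the transformed
  season inside the calendar year and prevent degenerate flat fits; hitting
  a bound raises a warning and the pipeline treats boundary fits like any
  converged fit subject to the RMSE gate below.
* `h` is evaluated by linear interpolation; arguments outside the model
  grid are excluded from the loss rather than extrapolated.
* converged fits with RMSE above 0.1 index units are excluded as poor.
  The interaction between a converged-but-poor fit and the threshold
  search is not otherwise specified anywhere, so this gate is a package
  choice.

Interior stages map through the fitted transform,
`x = (d0 - tshift) / xscale`. Emergence and maturity come from threshold
crossings of the daily series: rising through -0.68, falling through -0.68
(maize) or -0.55 (soybean). Where multiple crossings exist the *last*
upward crossing before the fitted peak and the *first* downward crossing
after it are used — the tie-break is a package choice; crossings are
located by linear interpolation between daily points and rounded half-up.

### County aggregation

Pixel stage dates are averaged per county-year (dates first, rounded, then
durations recomputed from the rounded dates). Averaging durations first
would differ by at most a day after rounding; dates-first is the
implemented convention. Pixels require a crop fraction of at least 0.8,
read inclusively ("at least 80%").

### Exposure classification

Daily weather is aggregated over the half-open windows `[S1, S2)`,
`[S2, S3)`, `[S3, S4)`: means for temperatures, radiation, VPD and the
drought index; a sum for precipitation. The standardized precipitation
anomaly divides each county-duration cell's total by its own across-year
mean and *sample* standard deviation, focal year included — the
normalization is not fully pinned down by its usual presentation, so
sample SD with the focal year included is the default and a leave-one-out
variant is provided (`include_focal = FALSE`). Temperature anomalies use
duration-mean maximum temperature, the same heat-stress variable the heat
panel variant removes.

The printed category bins ("-4.0 or less: Extreme Drought", "-2.0 to -2.9:
Moderate Drought", ...) leave the tenths between round numbers undefined;
the package closes them with half-open intervals whose *dry-side* bound is
inclusive, so -4.0 is Extreme Drought and -2.0 is Moderate Drought, and the
wet-side analogously ("+4.0 and above"). The bins then partition the real
line exactly, which the tests verify against a brute-force linear scan.

### Yield anomalies

Three expected-yield models are fitted by ordinary least squares:

* **C1**: `yield ~ county intercepts + common trend + 12 weather slopes`
  (Tmax, Tmin, radiation, VPD for each duration). Precipitation is
  deliberately excluded so drought losses stay in the residual. The
  per-duration sum is read as a sum over the three durations, not as
  polynomial powers of one seasonal mean — the superscript notation is
  ambiguous but only the duration reading matches the duration-wise
  weather aggregation.
* **C2**: an independent linear trend per county; this matches the
  per-county detrending language used for the group comparisons.
* **Ctemp**: as C1 but with precipitation included and maximum temperature
  excluded, for heat-priming detection.

The C1 trend is a single common slope plus county intercepts (whether the
trend should be county-specific is unstated; the common-slope reading is
implemented, and C2 supplies the fully county-specific alternative). Years
are centered at the panel's first year for conditioning. Rank-deficient
designs raise an error naming the offending columns. No clustered or
spatial standard errors are computed — inference on the panel coefficients
is not the package's goal.

### Group delineation and mitigation

County-years are grouped by their exposure sequence. For the drought index:
priming = D1 < -2, -2 < D2 < 2, D3 < -2; nonpriming differs *only* in D1
(-2 < D1 < 2); control is near-normal everywhere. All window comparisons
are strict: a value exactly on a bound falls outside. Two places in the
source material disagree about windows, and the package picks one with a
switch for the other:

* the nonpriming D1 drought window is (-2, 2) by default (the tabulated
  rule), with `pdsi_d1_variant = "text"` giving the narrower (0, 2);
* for heat groups the priming D1/D3 windows are (0.5, 2.0) — requiring
  actual early heat exposure, consistent with the priming hypothesis —
  rather than the tabulated (-0.5, 2.0), which would label a county-year
  "heat-primed" without any early heat.

Groups are compared with Welch's unequal-variance t-test (the two-sample
test is not otherwise specified) and one-way ANOVA at the 0.05 level, with
no multiple-testing correction applied. The mitigation metrics are plain
group-mean arithmetic; the fraction is reported as undefined when the
nonpriming loss is not positive. Analyses run independently per index
(drought index, precipitation anomaly, heat anomaly); county-years
qualifying under several indices are not cross-excluded.

## The synthetic-data generator

The generator is the package's study system: every distributional choice
below is fixed once and the tests run against it.

* **Canopy curves** are double logistics in day-of-year whose rise crosses
  the emergence threshold exactly at stage 1 and whose fall crosses the
  maturity threshold at stage 4, between a bare-soil baseline of -0.85 and
  a peak of 0.08 index units. All curve time constants are affine
  combinations of the stage dates, and simulated stage dates are affine
  (shift + scale) perturbations of the crop reference dates — county-year
  shifts of SD 3 days, scale SD 0.03, plus pixel-level shifts of SD 2 days.
  Every synthetic curve is therefore an exact time-affine transform of the
  reference shape, i.e. a member of the family the registration estimates;
  zero-noise recovery is then exact up to rounding, and recovery error
  under noise measures the estimator, not a family mismatch.
* **Reflectance** inverts the index: NIR tracks canopy between 0.18 and
  0.50, red follows from the index value. Compositing noise (SD 0.02 by
  default, 0.03 in the stress tests) is added to the index; a configurable
  fraction of composites is flagged bad and corrupted.
* **Weather** uses smooth seasonal climatologies (summer Tmax 30 C, winter
  0 C; radiation 90-260 W/m2; VPD 0.3-1.2 kPa) with county offsets and
  daily noise. Rain falls on half the days with gamma-distributed amounts
  (mean 6 mm, shape 2 — right-skewed but less variable than exponential),
  with a wetter spring and drier late summer (+/-20%).
* **Drought proxy**: the package does not re-derive the Palmer recursion —
  downstream only the category bins matter — but standardizes a trailing
  25-day water balance (precipitation minus `0.25 * max(Tmax, 0)` demand)
  against its noise-free climatological expectation, scaled by 21 mm
  (approximately the SD of a 25-day precipitation sum under the
  climatology) and clipped to [-6, 6].
* **Stress windows**: labels are drawn per county-year (default
  proportions 0.3 control / 0.3 nonpriming / 0.3 priming / 0.1 other) and
  precipitation is scaled by 0.05 inside label-specific windows. Because
  the proxy is trailing, a window must *lead* its target duration to
  register there: the early window runs from 25 days before stage 1 to 15
  days before stage 2 (so the proxy decays back to near-normal inside D2),
  and the late window leads stage 3 by up to 25 days, capped so it cannot
  reach far into a short D2. With this geometry the assigned groups match
  the generating labels for about 90% of county-years, and essentially
  never cross between priming and nonpriming.
* **Yields**: county intercepts (SD 0.8 Mg/Ha) around 9.8 Mg/Ha (maize), a
  0.1 Mg/Ha/yr technology trend, small per-duration weather
  sensitivities applied to panel-centered covariates, a drought loss
  (default 1.0 Mg/Ha) for late-droughted county-years, recovery of a
  configured fraction (default 0.5) for primed ones, and Gaussian noise
  (SD 0.3 Mg/Ha). Yields must stay positive or the configuration errors.
* **Ancillary tables**: weekly crop-progress ratios are exact logistics
  around the state-mean true stage dates (scale 3.5 days); crop fractions
  put ~10% of pixel-years below the 0.8 cutoff; LAI tables carry a +0.3
  canopy shift for primed maize county-years in D2.

What the generator does **not** emulate: spatial structure (counties are
exchangeable; no geography, no spatially correlated weather), reflectance
anisotropy or atmosphere beyond additive index noise, irrigation,
management heterogeneity, and any feedback of drought onto canopy
phenology (stress windows do not alter the reflectance curves). Passing
tests therefore demonstrate that the estimators recover the effects they
target under the stated noise — not that those effects are identified in
real satellite data, where drought shifts phenology itself and exposure is
spatially confounded.

## The crop simulator

The mechanistic cross-check is a deliberately small daily water-balance
model, not a reimplementation of a full crop model. Reference ET is
temperature-based (Hargreaves-type, radiation-equivalent 15 mm/day);
demand is `kc = 1.25` times reference ET scaled by potential canopy cover.
Supply comes first from a finite deep-moisture reserve — capacity
`soil_whc * (max_root_depth - base_root_depth)` = 288 mm — drawn at up to
3.5 mm/day scaled by how far roots have grown beyond their 0.4 m base
depth, then from a shallow store (capacity `soil_whc * base_root_depth` =
72 mm) recharged by rain. Stress is the unmet demand fraction; it
multiplies yield down through window sensitivities (0 vegetative, 0.02
early-reproductive, 0.028 late-reproductive per day of full stress — the
vegetative window carries none, reflecting that early stress alone should
not move yields) and accelerates root deepening while roots grow (first
two thirds of the season):

    growth = rate * (1 + (boost - 1) * stress),    boost >= 1.

With `boost = 1` growth is stress-independent and the mechanism is off;
this form (rather than `1 + boost * stress`) is required for the ablation
experiment to be a true null. Daily shallow-store conservation holds to
1e-9 mm by construction and is asserted in the tests; deep extraction is
reported as its own flux.

Scenario weather pairs control / nonpriming / priming realizations that
share every draw outside the scaled windows, and all three receive the
same 80 mm recharge storm two days after the early window closes. The
storm refills both stores in every scenario, so the *only* state the early
drought leaves behind is root depth — under ablation the priming and
nonpriming trajectories then coincide exactly, and with the mechanism on,
the yield gap is attributable to root depth alone. Demand uses potential
(not stress-reduced) canopy for the same reason: a stress-LAI-demand
feedback would leak early-drought memory around the mechanism. Reported
LAI still carries the cumulative-stress scaling.

Known limitations: no nitrogen, pests, phenology feedback or genotype
differences; absolute yields are not calibrated to any cultivar, and only
the qualitative ordering and the mechanism ablation are asserted.

## Problem sizes and numerical tolerances

The test suite and acceptance script use: 20 pixels x 5 years for stage
recovery (RMSE <= 1 day clean, <= 5 days at noise SD 0.03 with 10%
missing); 50 counties x 19 years x 100 replicates for panel-coefficient
calibration (99% CIs, >= 95% coverage per coefficient); 110 counties x 19
years (>= 500 county-years per compared group after exclusions) for the
end-to-end mitigation recovery, asserted within [0.4, 0.6] of the injected
0.5; 10,000 grid points for the classifier oracle; and 100 paired weather
draws for the simulator ordering. Exact identities (index arithmetic,
zero-noise least-squares recovery, registration of the model onto itself)
are asserted at 1e-8 or tighter; quantities limited by daily gridding and
rounding at half a day.
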