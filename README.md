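# primecrop

Does an early-season drought *prime* maize and soybean against a late-season
drought? Greenhouse studies suggest crops exposed to a mild early drought
lose less yield when a second drought hits during grain fill than crops hit
cold by a late drought alone. Testing this at the county scale requires a
chain of remote-sensing and econometric steps: detecting each county-year's
phenological calendar from satellite vegetation-index time series, windowing
the weather by those calendars, classifying drought exposure per
developmental window, removing trend- and weather-driven yield variation,
and comparing the residual yield anomalies of primed versus non-primed
county-years.

`primecrop` implements that full chain for users who want to study
priming-type stress-memory effects (agronomists, agro-climatologists,
remote-sensing scientists), exercised end to end on a seeded synthetic-data
generator with known ground truth, plus a minimal mechanistic crop simulator
that embodies the root-deepening explanation of the effect.

## The method

**Phenology.** Per pixel and year, the wide dynamic range vegetation index
is computed from red/NIR composites,

    WDRVI = (alpha * NIR - red) / (alpha * NIR + red),    alpha = 0.1,

smoothed to a daily series with a cross-validated smoothing spline, and a
crop-specific reference curve *h* is registered onto it by minimizing the
RMSE of

    f(x) = yscale * h(xscale * x + tshift)

with Levenberg-Marquardt. The two interior stages (maize: silking, dent)
map through the fitted transform, `x = (d0 - tshift) / xscale`; emergence
and maturity come from threshold crossings (rising -0.68; falling -0.68
maize / -0.55 soybean). County records carry stage dates S1..S4 and the
durations D1..D3 between them.

**Exposure.** Daily weather is aggregated over each duration; drought is
classified by the Palmer-index bins (from -4 "Extreme Drought" to +4
"Extremely Moist") and by the standardized precipitation anomaly
`x = (x_{y,t} - mean_t) / sd_t` per county and duration (heat analogously
from mean maximum temperature).

**Anomalies.** Three expected-yield models give residual anomalies:
per-county linear trends (C2); a fixed-effects panel with county
intercepts, a common trend and 12 weather slopes — Tmax, Tmin, radiation,
VPD per duration — with precipitation deliberately excluded so the drought
signal survives (C1); and a heat variant that omits Tmax instead (Ctemp).

**Priming.** County-years are grouped by their exposure sequence: *priming*
(drought in D1 and D3, near-normal D2), *nonpriming* (drought only in D3),
*control* (no stress anywhere). Welch's t-test and one-way ANOVA compare
the groups, and the mitigation arithmetic is

    mitigation_abs  = mean(priming) - mean(nonpriming)
    loss_nonpriming = mean(control) - mean(nonpriming)
    mitigation_frac = mitigation_abs / loss_nonpriming

## Worked example

```r
library(primecrop)
cfg <- simulation_config(seed = 11, n_counties = 12, years = 2000:2012,
                         pixels_per_county = 2)
report <- run_pipeline(cfg, anomaly_variant = "C2", index = "pdsi")
print(report)
```

```
priming analysis report (crop maize, variant C2, index pdsi)
  seed 11; 155 county phenology records
      group  n        mean        sd
    control 43  0.42638114 0.2759255
 nonpriming 50 -0.47183977 0.3410680
    priming 33 -0.04534273 0.2987016
  priming vs nonpriming: t = 6.01, p = 6.2e-08
  mitigation: 0.426 Mg/Ha of 0.898 Mg/Ha loss (frac 0.475)
```

The generator injected a 1.0 Mg/Ha loss for late-droughted county-years and
let primed county-years recover half of it. The pipeline — phenology
detection, duration climate, drought classification, per-county detrending,
group comparison — recovers that design: non-primed county-years sit about
0.9 Mg/Ha below the controls, primed ones recover 0.43 Mg/Ha of the loss
(estimated mitigation fraction 0.475 vs the injected 0.5), and the
priming/nonpriming difference is highly significant.

The same stages are available as numbered scripts under `analysis/`
(`01_simulate.R` ... `06_cropsim.R`), each writing its tables under
`results/`.

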