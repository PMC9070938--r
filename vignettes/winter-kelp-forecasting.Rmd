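---
title: "Winter ocean conditions as predictors of summer bull kelp canopy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Winter ocean conditions as predictors of summer bull kelp canopy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nereocast)
```

## The scientific problem

Bull kelp (*Nereocystis luetkeana*) is an annual canopy-forming kelp whose
northern-California population collapsed in 2014 and has not recovered. Its
summer surface canopy can be measured from Landsat at 30 × 30 m resolution,
giving a ~30-year annual abundance proxy; its microscopic overwintering
stages are hypothesised to be sensitive to winter ocean conditions
(temperature as a proxy for nitrate, upwelling-driven nutrient supply). This
package implements the full chain needed to test that hypothesis and to use
it for forecasting:

1. **QC/aggregation** of pixel canopy records into annual regional extent;
2. **seasonal predictors** from monthly ocean indices, with the fall season
   lagged to the year before the summer canopy;
3. **regression screening** of every (region, index, season) candidate with
   a significance mask and AIC selection;
4. **leave-one-out validation** (precision and predictability error);
5. **forecasting** from models trained only on pre-collapse years, to ask
   whether the environment still explains the observations afterwards;
6. a **synthetic-data generator** that stands in for the satellite and
   index datasets with known ground truth.

## Canopy QC and aggregation

A satellite pixel with no observation (cloud, sensor QC) is indistinguishable
from open water, so missing data must not be counted as zero kelp. The rules,
all configurable with these defaults:

* The 38–40 °N coastal domain is cut into **0.1° latitude bands**
  (half-open intervals, indexed from the southern origin). The regional split
  at Point Arena (39 °N) assigns a band to the north exactly when its lower
  edge is ≥ 39; hence 39.00 °N itself is northern.
* For each band, the **median number of data pixels** across years is the
  reference coverage. A band-year with strictly fewer than **90%** of that
  median is flagged missing; a count exactly at the threshold survives. An
  even number of years uses the mean of the two middle counts.
* A region-year with more than **10%** of its active bands flagged is
  missing; otherwise the extent is the sum over unflagged bands, converted
  to km². The flagged-band count is the numerator because the band is the
  unit at which missingness is decided; pixel-level fractions are no longer
  recoverable after band flagging. Flagged bands in an accepted year are
  simply omitted (no infilling or rescaling), which makes accepted years a
  slight underestimate — documented rather than corrected, as any infill
  would invent data.
* An observed **zero is data**: it enters the pixel count and adds nothing
  to the sum. Only regions that contain at least one band are reported;
  requesting an empty region is an error naming the region.

## Seasonal predictors

Monthly indices (MOCI for the southern/central/northern California regions,
buoy SST, BEUTI at three latitudes) are averaged over three-month seasons
aligned to the *kelp year* — the calendar year of the summer canopy
observation: winter = Jan–Mar, spring = Apr–Jun, summer = Jul–Sep of the
kelp year, and fall = Oct–Dec of the **previous** year (the last season to
finish before winter). A season with any of its three months absent is
missing: with only three months per season a partial mean is badly biased,
and no partial rule is defensible. Regression pairs are complete cases only,
in ascending year order.

## Regression, masking, selection

Each candidate model is univariate OLS of annual extent (km²) on one
seasonal predictor. Significance is the two-sided t-test on the slope with
n − 2 degrees of freedom (identical to the model F-test in the univariate
case, so the choice is moot); cells with p ≥ α = 0.05 are masked. No
multiple-testing correction is applied across the screen — a deliberate
caveat, matching the per-cell convention of the screening table this
reproduces; with 64 cells, ~3 false positives are expected under a global
null.

Model selection minimises AIC among significant candidates. Because AIC
conventions differ by additive constants, the package pins one and computes
it itself:

$$\mathrm{AIC} = n \log(2\pi\,\mathrm{SSE}/n) + n + 2k, \qquad k = 2.$$

This is the full Gaussian maximum-likelihood form counting slope and
intercept; only differences at equal *n* are meaningful. A perfect fit
(SSE = 0) returns −∞ so it always wins — and residual sums below
`1e-12 × SST` are snapped to zero first, so an exactly linear input is
treated as exact rather than as rounding noise. Ties on AIC break by higher
R², then lexicographic index name, making selection deterministic and
invariant to candidate order.

## Validation and forecasting

Leave-one-out refits the selected model *n* times, each with one year held
out. Two statistics come out of it, kept distinct deliberately: **precision**
is the mean of the refits' in-sample R² (read this way because those values
are expected to track the full-period R², which only holds for in-sample
refits, not predictive R²), and the **predictability error** of a year is
|measured − predicted| / measured × 100 for the held-out prediction. Small
measured denominators are used raw — collapse-era observations are close to
zero and the resulting triple-digit percentages are the signal, not an
artifact; only an exactly-zero measurement is undefined (flagged, excluded
from aggregates, warned about).

Forecasting trains on the pre-collapse period (default 1991–2013) and
predicts 2014 onward. A guard refuses any forecast year found in the
training set. Raw predictions may be negative; errors are computed from the
raw value (the large post-collapse errors are only reproducible that way)
and a clipped `max(0, raw)` column is reported alongside, since physical
extent is nonnegative.

## The synthetic world

The generator's defaults state one world and are not tuned per test:

* **Indices**: zero-mean unit-variance monthly AR(1) latent factors,
  interpreted as warm-positive thermal anomalies, with common cross-index
  correlation 0.6. The AR coefficient is set so that adjacent seasonal means
  correlate at 0.8 (φ ≈ 0.90), the documented strong winter–spring
  persistence of these indices; `ar1_coef_for_season_cor()` inverts the
  closed-form block-mean correlation. MOCI-like series are the latents; SST
  is `11.6 + 0.8 × latent` °C (winter range off Point Arena); BEUTI is
  `−5 × latent` (upwelling opposes warm anomalies). These signs keep the
  field's conventions: kelp–SST slopes negative, kelp–BEUTI positive.
* **Kelp link**: regional truth is `max(0, α + β·winter + ε)` with the
  selected winter models' published scale as defaults — north α = 3.04,
  β = −0.77 with noise giving expected R² 0.87; south α = 5.52, β = −0.19
  with expected R² 0.57. `noise_sd_for_r2()` solves the variance identity
  for the noise. Truncation at zero is a deliberate deviation from pure
  linearity; at the default calibration zero lies ~3.9 standard deviations
  below the mean, so it essentially never binds.
* **Pixels**: truth is spread over the region's bands by a fixed unimodal
  (discretised Gaussian) weight profile — kelp is patchy, and non-uniform
  bands exercise the QC — then filled deterministically into 900 m² pixels
  (full pixels, one partial, observed zeros). 1200 pixels per band leaves
  capacity headroom; exceeding capacity is a configuration error, never a
  silent truncation.
* **Clouds**: each band-year is hit with probability 0.08, losing a random
  30% of its pixels (enough to trip the 90% rule). These two numbers were
  chosen once so that ~20% of region-years fail QC, matching the 5–7
  missing years out of 30 in the observed record.
* **Regime shift**: from the split year (2014), observed canopy is
  multiplied by a suppression factor (default experiments use 0.1) while
  the environment is untouched — the herbivory-decoupling stand-in.

What the generator does **not** emulate: spatial ocean structure, ENSO-scale
decadal dynamics, differences between the three MOCI regions beyond a common
correlation, urchin population dynamics, or autocorrelated kelp residuals. A
green test therefore establishes that the pipeline's statistics are correct
and that its qualitative conclusions follow in a world whose assumptions
match the model family — not that the real coastline satisfies those
assumptions.

## Worked example

```{r, eval = FALSE}
cfg <- scenario_config(suppression_factor = 0.1)
sc <- simulate_scenario(cfg, seed = 42)
report <- run_full_analysis(sc$pixels, sc$indices)
report$models$equation
report$forecast[, c("year", "predicted_km2", "observed_km2", "error_pct")]
```

The numbered scripts under `analysis/` run the same sequence stage by stage,
writing every table under `results/`.

## Known limitations

* Inference assumes independent Gaussian errors; annual series this short
  carry autocorrelation the p-values ignore.
* The screen's cells share data, so neighbouring R² values are correlated;
  the type-I-rate guarantee is tested under independent-noise predictors.
* With season-to-season persistence at its default 0.8, the lagged fall
  season is almost as informative as spring in the synthetic world —
  stronger than in the observed system, where fall relationships are weak.
* Precision and predictability error summarise one model per region; no
  model averaging or multivariate extension is attempted.
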