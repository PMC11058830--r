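# hydroscale

Multi-timescale analysis of monthly hydro-climatic and vegetation series:
how does a lake's water level (and area) relate to temperature,
precipitation and vegetation greenness (NDVI) when each of those variables
mixes sub-seasonal noise, a 12-month seasonal cycle, multi-year oscillations
and long-term trend — and when the drivers act with lags and over
accumulation windows?

The package implements the full analysis chain as reusable, tested
functions, and ships a synthetic-data module that generates coupled monthly
systems (and raster stacks) with *known* periods, trends, break points, lags
and accumulation windows, so every stage is validated by recovering planted
ground truth. It is written for researchers analysing lake/catchment
monthlies (level, area, NDVI, climate) who want the method chain without the
proprietary source datasets.

## Methods

- **EEMD decomposition** (`emd`, `eemd`, `group_imfs`). Empirical Mode
  Decomposition extracts intrinsic mode functions (IMFs) by sifting with
  cubic-spline envelopes (mirror-extended boundaries, fixed 10 sifting
  iterations per IMF); the ensemble version averages IMFs across
  noise-perturbed copies (default 100 members, noise sd = 0.2 × sd(x)).
  Each IMF's mean period is `T = 2L / n_extrema`; IMFs are grouped into
  noise (`T` < 6 months), annual (6 ≤ `T` < 24) and interannual
  (`T` ≥ 24, plus residual) components that sum to the input exactly.
- **Trend and variability** (`theil_sen`, `mann_kendall`,
  `coefficient_of_variation`, `pixelwise`). Theil–Sen median slope
  (median over all pairwise slopes), Mann–Kendall S with tie-corrected
  variance and continuity-corrected z, trend classes at ±0.0005 yr⁻¹, and
  CV volatility classes (0.05/0.10/0.15/0.20 thresholds) — scalar or per
  pixel of a raster stack, plus vegetation masking (growing-season NDVI ≥
  0.1) and water-frequency mapping.
- **Change points** (`detect_change_points`, `fit_segments`). PELT (exact
  penalized optimal partitioning, Gaussian mean-shift cost, MBIC-style
  3·log n penalty), greedy binary segmentation, and a continuous
  piecewise-linear (kink) search for rate changes; per-segment OLS slopes
  and R².
- **Coupling** (`partial_correlation`, `tl_ta_search`,
  `component_coupling`, `seasonal_curve`). Partial correlation by
  residualization, searched over a joint time-lag (TL-0..3) ×
  time-accumulation (TA-0..3, rolling sums) grid, with the other predictors
  as controls held at their own best transforms; best-cell p-values are
  flagged as selection-biased. Seasonal curves are calendar-month means
  normalized on the sum of amplitudes.
- **Synthetic systems** (`synthetic_config`, `gen_coupled_system`,
  `gen_trend_raster`, `gen_water_stack`). Harmonics + piecewise trends +
  AR(1) noise; responses built from lagged/accumulated drivers with known
  coefficients; ground truth emitted as a JSON sidecar.

## Worked example

```r
library(hydroscale)

cfg <- synthetic_config(n_months = 240, start = c(2001, 1), seed = 20260901)
system <- gen_coupled_system(cfg)   # temperature, precipitation, ndvi, level, area

d  <- eemd(system$series$level, eemd_settings(ensemble_size = 100, seed = 1))
print(d)
#> <decomposition> 6 IMFs + residual (n = 240)
#>   IMF 1: 155 extrema, mean period 3.1 months
#>   IMF 2: 40 extrema, mean period 12.0 months
#>   ...
group_imfs(d)
#> <scale_components> noise: IMF 1 | annual: IMF 2,3 | interannual: IMF 4,5,6 + residual
```

The analysis scripts run the same chain end to end and print what they find:

```sh
Rscript analysis/01_simulate.R            # plant the ground truth
Rscript analysis/02_decompose.R           # EEMD + grouping per variable
Rscript analysis/03_trends_changepoints.R # Sen/MK/CV, segmentation, raster demo
Rscript analysis/04_coupling.R            # TL/TA partial-correlation tables
```

The final script prints the coupling table for the annual components; on
the shipped seed it recovers the planted truth exactly:

```
  response     predictor component lag accum      r   p_value   n significant
1    level   temperature    annual   0     0  0.589  4.16e-23 235        TRUE
2    level precipitation    annual   3     0  0.329  2.48e-07 237        TRUE
3    level          ndvi    annual   0     3 -0.946 1.27e-114 235        TRUE
Planted truth (level): temperature TL-0-TA-0 (+); precipitation TL-3-TA-0 (+); ndvi TL-0-TA-3 (-)
```

i.e. lake level tracks temperature synchronously and positively, follows
precipitation with a 3-month lag, and relates negatively to NDVI
accumulated over the preceding 3 months — exactly the structure the
generator planted. Tables land under `results/`.

## Layout

- `R/` — the implementation; `tests/testthat/` — unit, property and
  acceptance tests; `analysis/` — numbered narrative drivers;
  `vignettes/multiscale-lake-analysis.Rmd` — the methods vignette
  (model, assumptions, parameter choices, limitations).
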