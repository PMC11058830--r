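---
title: "Multi-timescale decomposition and coupling analysis of lake monthlies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale decomposition and coupling analysis of lake monthlies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroscale)
```

## The problem

A lake integrates its catchment: water level and area respond to
temperature, precipitation and vegetation with delays (routing, snowmelt)
and over accumulation windows (soil moisture, cumulative rainfall), while
every monthly series mixes sub-seasonal noise, the 12-month cycle,
multi-year oscillations and long-term trend. Correlating raw monthlies
conflates these timescales. The chain implemented here separates them
first (EEMD), characterizes trend and variability per scale (Theil–Sen,
Mann–Kendall, CV classes), segments regime changes (change-point
analysis), and only then asks the coupling question scale by scale with
partial correlations over a lag/accumulation grid.

Everything is validated against synthetic systems with planted truth; the
real remote-sensing and altimetry products such analyses usually start
from are deliberately out of scope.

## Decomposition (EMD / EEMD)

EMD extracts intrinsic mode functions (IMFs) by sifting: cubic-spline
envelopes through the strict interior maxima and minima, subtract the
envelope mean, repeat. Our numerical choices, where the method family
leaves room:

- **Sifting stop.** A fixed count of 10 sifting iterations per IMF rather
  than an SD-threshold. A fixed count is deterministic and keeps ensemble
  members structurally comparable, which matters because EEMD averages
  IMFs position-wise across members.
- **Boundary handling.** The two nearest extrema are mirrored beyond each
  end before spline fitting — the standard anti-divergence treatment for
  envelopes on finite records.
- **Plateaus.** A run of equal values bounded by lower (higher) neighbours
  counts as one extremum at the plateau midpoint, so ties cannot inflate
  the extrema count.
- **Termination and degenerate inputs.** Extraction stops when the
  residual has fewer than two interior extrema (or fewer than two maxima
  or minima, where no envelope pair exists). A monotone ramp yields zero
  IMFs and residual = input; a constant likewise. The additive identity
  (sum of IMFs + residual = input) holds to floating-point tolerance by
  construction and is asserted below 1e-9 in the tests.
- **Ensemble defaults.** 100 members, added white noise with sd = 0.2 ×
  sd(input), and a common IMF count of floor(log2 n) − 1 per member
  (members that exhaust early contribute zeros). These are the customary
  ensemble settings for monthly geophysical records. The EEMD residual is
  defined by subtraction (input − sum of averaged IMFs) so the identity
  stays exact despite averaging. A noise ratio of 0 short-circuits to
  plain EMD, bit for bit.

**Mean period.** The period of an IMF is estimated from its extrema count:
`T = 2L / n_extrema` months, exact for sinusoids (one maximum and one
minimum per cycle). The field sometimes words this rule as a count
"divided by twice the record length", which literally defines the
*frequency*; we implement the reciprocal and report both the count and
`T`, so the convention is auditable in the output tables.

**Grouping.** IMFs with `T` < 6 months are summed into the noise
component, 6 ≤ `T` < 24 into the annual component, and `T` ≥ 24 plus the
residual (and any IMF with undefined period) into the interannual
component. The half-open convention resolves the boundary ambiguity one
meets in the literature ("6 < T < 24" vs "between 6 and 24"); both cutoffs
are arguments of `group_imfs()`. The three components partition the
reconstruction exactly. The noise component is retained in all outputs but
excluded from coupling analysis by default.

## Trend, variability and water-frequency statistics

- **Theil–Sen** is the median of all pairwise slopes over month indices;
  missing months keep their index so irregular observation does not bias
  the slope. Annualized slope = 12 × monthly.
- **Mann–Kendall** uses the closed-form S with tie-group-corrected
  variance and the ±1 continuity correction; all-tied input returns S = 0,
  p = 1. p-values are reported raw — no multiple-testing correction across
  pixels, matching common practice in trend mapping; an FDR adjustment can
  be applied downstream if wanted.
- **Classes.** Annual slopes classify as improved (≥ 0.0005 yr⁻¹), stable,
  degraded (≤ −0.0005 yr⁻¹); the boundary value goes to improved/degraded
  because the published class definitions overlap at exactly |slope| =
  0.0005 and the directional reading is the informative one. CV =
  sample (n−1) sd / mean, computed by default on yearly growing-season
  (March–October) means, with five volatility classes at
  0.05/0.10/0.15/0.20; lower bounds inclusive.
- **Vegetation mask.** A pixel is stable vegetation when its
  growing-season mean NDVI ≥ 0.1 (inclusive) in every year; a
  mean-of-years mode is available because yearly strictness is the more
  conservative of the two defensible readings.
- **Rasters.** A pixel missing in more than 10% of time steps is excluded
  from per-pixel statistics — a conservative default where the upstream
  convention is unstated. Water frequency is the percentage of valid
  months classified water; permanent = exactly 100%; the at-risk fraction
  is the share of wet-ever pixels strictly between 0 and 100%.

## Change-point segmentation

Lake histories are segmented two ways:

- **Mean shifts** — PELT, the exact penalized optimal partitioning with
  pruning, under a Gaussian mean-change cost. The series is standardized
  by a robust noise estimate (MAD of first differences / √2) and the
  default penalty is 3·log n, in the spirit of MBIC defaults of the
  standard change-point toolboxes. The tests verify PELT against
  exhaustive search on every instance with one admissible break.
- **Rate changes** — a greedy knot search for a *continuous*
  piecewise-linear (linear-spline) fit, with coordinate-wise refinement of
  each knot. Continuity is load-bearing: with unconstrained per-segment
  lines, a slope-only break can be misplaced by tens of months at almost
  no cost (two free lines fit a kink equally well almost anywhere —
  verified against an exhaustive-search oracle), whereas a misplaced
  spline knot forces lack of fit on both sides. Since the physical series
  being segmented (a lake's level) is continuous, the constrained model is
  also the right generative assumption. Per-segment rates and R² are then
  reported from ordinary per-segment OLS, which is how multi-phase lake
  histories are usually quoted.

Minimum segment length defaults to 12 months — sub-annual "phases" in a
multi-decadal lake history are seasonal structure, not regimes.
Breakpoints are reported as the 1-based index of the first month of the
new segment, and as calendar months when the input carries a calendar.

A statistical caveat the tests encode explicitly: break-location precision
is limited by the slope change relative to noise (location sd on the order
of (σ²/δ²)^(1/3)). A steep-to-flat transition is localizable to months; a
flat-to-slightly-rising bend only to tens of months, under any estimator.
The recovery tests therefore hold the sharp kink to ±10 months and the
subtle one only to its feasible precision.

## Coupling: partial correlation over the TL/TA grid

The response is correlated with each predictor transformed by every
combination of time lag (TL-k: value k months earlier) and
time accumulation (TA-m: rolling sum over the m-month window ending at the
lagged month), k, m ∈ 0..3. Grid bounds default to 3 months because
longer memory is not interpretable at monthly resolution in this setting.
Conventions:

- **TA-0 vs TA-1.** Both denote a single-month window (the window is
  max(m, 1) months), so the two columns tie exactly; ties break toward
  the smaller lag + accumulation, then the smaller lag, making the search
  deterministic. Accumulation is a rolling *sum*, consistent with
  "cumulative precipitation"; correlation is scale-invariant, so sum vs
  mean is immaterial for r.
- **Partial correlation** is computed by residualizing response and
  predictor on the controls (with intercept) and correlating the
  residuals; p from t = r·sqrt(df/(1−r²)), df = n − 2 − #controls. The
  matrix-inverse identity (−Ω₁₂/√(Ω₁₁Ω₂₂)) serves as an independent
  cross-check in the tests, never as the implementation.
- **Controls.** Each predictor is tested with the remaining predictors as
  controls. Control transforms are found by one iteration: a first pass
  searches every predictor with the others untransformed, then the final
  pass holds each control at its first-pass best (lag, accumulation).
  This mattered empirically in the design phase: shared 12-month
  harmonics make bivariate grids phase-confounded, and mis-transformed
  controls leak a collinear seasonal signal into the partial correlations.
  A raw-controls mode is available as a config switch.
- **Selection bias.** The best cell maximizes |r| over a 16-cell grid, so
  its p-value is the minimum of a search and is biased low. Every result
  object and report carries this flag; the 0.05 threshold on the best
  cell should be read as descriptive, not inferential.

Seasonal curves (calendar-month means of the annual component, divided by
the sum of their absolute values so Σ|values| = 1) make phase comparisons
across variables of different units; the normalization constant is kept in
the result for back-conversion.

## The synthetic generator — what it emulates, what it does not

`gen_coupled_system()` builds drivers as 12-month harmonics plus AR(1)
noise and responses as linear combinations of lagged/accumulated drivers
plus a piecewise-linear trend plus AR(1) noise. Defaults describe an
arid-zone lake system at monthly resolution:

- temperature: amplitude 10 °C around 8 °C, peak in June; precipitation:
  amplitude 15 mm around 25 mm, peak in July; NDVI: amplitude 0.15 around
  0.3, peak in August;
- driver AR(1) noise with φ = 0.3 and sd = half the seasonal amplitude —
  monthly climate records carry a substantial stochastic share, and that
  share is also what makes a lag identifiable at all (a pure tone's lag is
  indistinguishable from a phase shift);
- planted couplings for level/area: temperature synchronous and positive,
  precipitation lagged 3 months and positive, NDVI accumulated over
  3 months and negative;
- response noise: AR(1), sd = 0.3 × sd of the deterministic coupled
  signal;
- level trend: decline (−0.06 m/month) / stable / slight rise
  (+0.005 m/month) in three equal phases.

Raster generators plant per-pixel slopes and CV targets
(`gen_trend_raster`, noise variance adjusted for the trend's own
contribution) and permanent/fringe water bodies with exact pixel counts
(`gen_water_stack`). Ground truth always travels with the data as a JSON
sidecar.

What the generator does *not* emulate: non-stationary seasonality,
multiplicative or skewed noise (precipitation is truncated-normal-ish in
reality, not Gaussian), spatial autocorrelation between raster pixels,
nonlinear or threshold couplings, and observation artifacts (sensor gaps,
cloud masks). Passing recovery tests therefore demonstrates that the
estimators do what they claim under linear-additive, Gaussian-AR(1)
conditions — not that any particular real-world attribution is correct.

## Problem sizes and determinism

Test and acceptance runs use 480-month series for decomposition and
coupling recovery (200 seeded systems for the recovery rates), 240 months
for conservation and step-recovery checks, 2,000 null simulations for
Mann–Kendall calibration, and 8×8–24×24 raster demos — sizes at which
every property is statistically sharp while a full run of suite plus
acceptance script completes in about a minute. All randomness flows from
explicit seeds; generators and the pipeline are bit-reproducible under a
repeated seed (asserted byte-for-byte on the written CSVs), and
`local_seed` scoping keeps package RNG use from disturbing the caller's
stream.

## Known limitations

- EEMD only; the complete-ensemble (CEEMDAN) and multivariate variants
  are out of scope, as is any IMF significance test against a white-noise
  spectrum.
- Mode mixing can still leak tone energy between adjacent IMFs; grouping
  by mean period absorbs most of it, which is precisely why downstream
  analyses consume the grouped components rather than single IMFs.
- PELT here covers mean shifts with a Gaussian cost; variance-change and
  nonparametric costs are not implemented, and break locations carry no
  confidence intervals.
- The TL/TA grid treats lag and accumulation as integers ≤ 3 months;
  sub-monthly or longer-memory dynamics are invisible at this design.
- Raster support is same-grid stacking only (CSV/TIFF); no reprojection,
  no NetCDF, no geospatial metadata beyond the monthly time axis.
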