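---
title: "Bagged SARIMA counterfactuals for intervention effects on weekly pollution series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bagged SARIMA counterfactuals for intervention effects on weekly pollution series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagsarima)
```

## The problem

An abrupt, dated policy intervention — here, a state-level emergency
declaration early in a pandemic — changes behaviour overnight, and with it
the emissions that drive ambient concentrations of NO~2~ (ppb) and PM~2.5~
(µg/m³). Simply comparing concentrations before and after the date
confounds the intervention with seasonality, long-run trends, weather, and
serial correlation. The quasi-experimental alternative implemented here is
*counterfactual forecasting*: train a time-series model only on
pre-intervention history, forecast what concentrations would have been had
nothing happened, and read the intervention effect off the gap between
observation and forecast.

## The model and the pipeline

Each state × pollutant series is weekly: `value` is the mean concentration
over a 7-day bin, aligned with weekly mean temperature, precipitation and
humidity. The training window (five years, 260 weeks at full scale) is
followed by a 16-week forecast period containing the intervention.

The pipeline has four stages, each a package function:

1. **Bootstrap ensemble** (`generate_ensemble`). The training series is
   Box-Cox transformed (λ chosen on [0, 1] by Guerrero's
   coefficient-of-variation criterion on per-period subseries, overridable),
   decomposed by STL into trend + seasonal + remainder, and the remainder is
   moving-block resampled. Each recomposed, back-transformed series is one
   bootstrap replicate of the training history; B = 1000 at full scale.

2. **SARIMA with weather covariates** (`select_order`,
   `fit_and_forecast`). Orders (p,d,q)(P,D,Q)~m~ are chosen on the original
   training series by a stepwise search minimizing the bias-corrected AIC;
   seasonal differencing comes from the seasonal-strength heuristic
   (threshold 0.64) and ordinary differencing from repeated KPSS level tests
   (5% critical value 0.463). Temperature, precipitation and humidity enter
   as exogenous linear regressors. Each replicate is then re-estimated with
   the selected orders fixed and forecast over the horizon using the
   *observed* future weather — the counterfactual removes the intervention,
   not the weather.

3. **Bagging** (`bag_forecasts`). The counterfactual for week *i* is the
   arithmetic mean of the replicate forecasts; the 2.5/97.5 percentile of
   the replicate paths gives a 95% band. Each replicate path is a draw from
   the fitted model's predictive distribution: the mean forecast plus a
   simulated future-innovation path built from the model's ψ-weights
   (MA(∞) expansion, including the seasonal and differencing operators), so
   the replicate spread carries forecast noise as well as
   training-resampling uncertainty. Without that term the percentile band
   would only reflect parameter/resampling variation and would visibly
   under-cover held-out observations.

4. **Effects** (`compute_deviations`, `estimate_effect`). Weekly deviations
   are δ~i~ = C^obs^~i~ − C^pred^~i~. With the intervention in forecast week
   *t*, the effect is the difference of window medians,
   Δ = median(δ~before~) − median(δ~after~); under this sign convention a
   positive Δ is a post-intervention decline. The CI is the percentile
   interval of the same statistic over the replicate-level deviation series,
   and the effect is significant when the interval excludes zero. A Wilcoxon
   rank-sum before/after comparison is attached as a sensitivity diagnostic.

Crucially, stages 1–3 never see the intervention date; it enters only in
stage 4. This agnosticism is enforced structurally (the forecasting
functions take no calendar argument) and asserted in the test suite by
bit-identity of the forecast with and without a calendar.

Model adequacy is tracked by the signed average prediction error
(APE = mean of the 16 deviations, which a validation run on the final
pre-intervention year should center near zero) and by the in-sample MASE —
mean absolute error scaled by the one-step naive error on the same training
window, so values below 1 beat naively carrying last week forward.
`validation_run` repeats the full machinery with the split shifted one
horizon back, training through the penultimate year only.

Cross-pollutant contrast uses ρ = Δ~NO2~/Δ~PM2.5~ (`compute_ratio`);
negative values flag states where the two pollutants moved in opposite
directions. A zero denominator yields an explicit undefined marker rather
than an error, since a genuinely null PM~2.5~ effect is a legitimate
outcome.

## Heterogeneity regression

Per-state effects are regressed on state covariates: 2014 emissions-source
shares (fire, stationary, mobile — the biogenic share is dropped, so the
three do not sum to 1), log population density, and Census region, with all
two-factor interactions (`build_design`, `fit_wmlr`). The fit is weighted
least squares. Choices the method description leaves open, resolved here:

* **Weights** — inverse bootstrap variance of each state's Δ̂. This is the
  single most consequential free choice; an equal-weights fit is always
  reported alongside as the sensitivity run, and estimates are invariant to
  rescaling all weights.
* **Density** is log-transformed (right-skewed across states); continuous
  predictors are centered before interactions are formed, decorrelating
  main effects from interactions.
* **Region** uses four Census regions, first level as reference. A
  single-level region factor is dropped with a warning; rank-deficient
  columns are dropped and reported.

## The synthetic-data generator

`simulate_state_series` emulates the structure of the real inputs with
known ground truth: concentration = baseline + linear trend + sinusoidal
seasonality + additive weather effects (centered covariates × known
coefficients) + AR noise, with an exact level drop `delta_true` injected
from the intervention week onward, and flooring at zero.
`simulate_state_covariates` draws source shares on the simplex
(Dirichlet), assigns regions in balanced rotation, and generates effect
outcomes from a known coefficient vector with heteroscedastic noise whose
true SDs are returned for weight construction.

Defaults mirror the full-scale study design: five years of history at a
52-week cycle, a 16-week forecast period, intervention in week 9 (so the
before/after windows are 8 + 8, inside the design's 8–10 / 6–8 week
range), injected declines drawn from U(1, 8) concentration units, AR(1)
noise with coefficient 0.5 and unit innovation SD, seasonal amplitude 3.
Baselines are kept well above `delta_true` because the non-negativity
floor would otherwise bias the injected shift. Seeding is hierarchical: a
single master seed plus stable string hashing of (state, pollutant,
replicate) labels gives reproducible, collision-free streams per state.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: spatial correlation between states,
monitor-level sampling within states, non-sinusoidal or drifting
seasonality, measurement artefacts and missingness bursts, and any
feedback between weather and concentrations beyond the additive terms.

## Problem sizes, tolerances and numerical choices

The test suite and the acceptance studies run the generator at a 12-week
seasonal cycle (60-week histories; 300-week for the MASE study) with
B = 50 replicates, 20 states for effect recovery, 100 null runs for
calibration, and 40 states × 100 replicates for the weighted-regression
study — sizes chosen so the full battery completes in minutes on one CPU
while leaving Monte-Carlo error well inside the asserted bounds. The cycle
length and B are ordinary arguments; full-scale runs use 52 and 1000.

Numerical conventions worth knowing:

* Box-Cox on series containing zeros shifts by half the smallest positive
  value (removed after inversion); the inverse truncates `λz + 1` at a tiny
  positive floor so replicates of positive series stay positive. Round-trip
  identity is asserted to 1e-10 relative error.
* STL uses a periodic seasonal window by default (seasonality treated as
  stable across the training years); the additive identity of the
  decomposition is exact by construction and asserted to 1e-8.
* The moving-block bootstrap draws overlapping blocks (default 24 weeks,
  clamped to the series length) and trims a random offset; with block
  length equal to the series length the input is returned unchanged —
  the degenerate-case oracle.
* Order search caps default to p,q ≤ 3 and P,Q ≤ 1, D ≤ 1, d ≤ 2 with
  d + D ≤ 3 (estimability with ~5 seasonal cycles of history); ties go to
  fewer parameters because a candidate must beat the incumbent strictly.
  With `method = "CSS"` the search compares the conditional-sum-of-squares
  profile-likelihood AICc surrogate (n·log σ̂² + penalty), the standard
  fast approximation for long series.
* Orders are selected once on the original series and coefficients
  re-estimated per replicate (`spec_policy = "fixed"`); per-replicate
  re-selection is available but roughly two orders of magnitude costlier
  at full scale, and the fitted object records which policy produced it.
* Non-convergent replicates are dropped (never retried with jitter); if
  more than half fail, bagging aborts with the convergence rate.
* Weekly bins are half-open 7-day intervals anchored at the forecast start
  (Jan 1 at full scale, so a Jan 1 – Apr 23 window of 114 days yields 16
  whole weeks and drops the 2-day remainder). The week containing the
  intervention date belongs to the "after" window by default — the
  intervention acts within that week — and the boundary rule is a flag,
  since either convention differs by one week.
* Gaps of at most two consecutive missing weeks are linearly interpolated;
  longer gaps and boundary gaps are hard errors, never extrapolated.

## Known limitations

Percentile CIs from B = 50 replicates are noticeably granular; null
calibration sits near, not at, the nominal 5% (the acceptance study bounds
it at 10%). Effects are estimated per state with no multiplicity
adjustment across states, matching the per-state reporting convention of
the study design this package reproduces. The WMLR weights are a modelling
choice, not an identity — with few states and the full interaction design
the fit is heavily parameterised, which is why the residual degrees of
freedom are checked and the mains-only design is available. And the
counterfactual logic assumes trend, seasonality and the
weather-concentration relationship persist from training into the forecast
window; none of that is testable from inside the model.
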