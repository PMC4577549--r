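---
title: "Forecasting mortality from rates of improvement: models, defaults, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting mortality from rates of improvement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rmicast)
```

## The problem

Life expectancy at birth, e0, summarizes a period's age-specific death
rates m(x,t) through a life table. Forecasting e0 is easy when mortality
declines regularly and hard when it does not: populations that pass through
economic or political crises show long stagnations, abrupt working-age
mortality shocks, and delayed recoveries. Models that extrapolate log death
rates with a frozen age pattern — the Lee-Carter family — cannot represent
either the *dynamic age shift* of survival improvements toward older ages
or a *trend reversal* that has not yet happened in the target country but
is already visible in a comparable one.

This package represents mortality change in improvement-rate space,

ρ(x,t) = 100 · (1 − m(x,t) / m(x,t−1))   [percent per year],

positive when survival improves, and builds its forecasting model there.

## The improvement-rate model

The model is a reconstruction: the publication the design follows describes
its model's capabilities (dynamic age shifts; optional blending toward
reference-country trends; fully probabilistic output) but defers the
equations to a companion paper. Every concrete choice below is therefore a
documented decision of this package, with all constants in `rmi_config()`
and echoed into fits and forecasts.

**Signal extraction.** The observed surface is smoothed with tensor-product
cubic B-splines (knots every 5 ages and 5 years, order-2 difference
penalties, penalty weights 10/10) by penalized Poisson likelihood with a
log-exposure offset when death counts and exposures are available, by
penalized least squares on log rates otherwise. The penalty null space
contains every bilinear log surface, so Gompertz-like schedules with
constant improvement pass through unshrunk. Improvement rates are computed
from the smoothed surface.

**Trend.** For every age, ρ(x,t) = α_x + β_x (t − t̄) + ε_{x,t}, with an
order-2 difference penalty (weight `lambda_trend`, default 10) on the α and
β age profiles. Because the time regressor is centered, the α and β systems
decouple into two ridge-type solves; penalty 0 reproduces per-age OLS and
penalty → ∞ the best age-linear profiles. A positive β above the current
improvement peak and a negative β below it is exactly a peak migrating
upward in age, which the linear trend extrapolates.

**Reference blending.** References' improvement surfaces are pooled with
equal weights (the source work pools up to three reference countries
without stating weights) and given the same trend fit. The forecast blends
target and reference trends with w(h) = w_max (1 − e^{−h/τ}), default
w_max = 0.5 and τ = 10 years: the data of the country itself dominate the
near term; anticipated catching-up dominates the long run. w_max = 0
disables references entirely; τ ≤ 0 applies full weight from the first
forecast year.

**Simulation.** Rates cumulate from the jump-off column:
m(x,T+h) = m(x,T) ∏_{j≤h} (1 − ρ̂(x,j)/100), with ρ̂ clamped to ±25 % (a
warning of class `clamp_saturation` fires if more than 5 % of cells hit the
clamp). e0 is computed per draw and per year; quantiles at
0.025/0.10/0.165/0.25/0.5/0.75/0.835/0.90/0.975 support the 50/67/80/95 %
intervals.

## The uncertainty engine, and why it has four parts

A naive residual bootstrap of the smoothed improvement surface is badly
overconfident. Each component below fixes one identified, quantified
deficiency; none is a tuning knob:

1. **Moving-block bootstrap over years** (block length 2 × knot spacing
   = 10). The time smoother leaves residuals serially correlated over about
   the support of one B-spline; iid column resampling understates trend
   uncertainty by roughly √(block length).
2. **Finite-sample block-bootstrap correction** 1/√(1 − L/n): block means
   understate the variance of the full-sample mean by the factor (1 − L/n).
3. **Jump-off covariance.** Forecasts launch from the smoothed last-year
   rates (launching from the raw column injects one year of Poisson noise
   into every forecast year). The smoother's sandwich covariance of the
   fitted log rates in the jump-off year is drawn from per path, with its
   full cross-age correlation.
4. **Age-correlated period shocks.** Future trend residuals are resampled
   whole residual columns rather than iid per-age Gaussians: period effects
   are correlated across ages, and iid noise would diversify away in e0 and
   understate interval widths, while the marginal per-age sd remains the
   reported σ_x.

With all four parts the 95 % e0 interval at a 10-year horizon covers the
latent truth of the regular synthetic scenario at close to nominal rate
(the calibration acceptance test checks the 88–99 % band over 200
replicates).

## Comparator models

`fit_lc()`/`forecast_lc()` implement Lee-Carter with (b, k) the first
singular pair of the centered log-rate matrix, Σb = 1, Σk = 0 enforced
exactly, drift (k_T − k_1)/(n−1), and k simulated as a random walk with
drift (drift uncertainty σ_rw/√(n−1) optional). Normalizing b by its own
sum makes the fit invariant to the SVD's sign ambiguity. There is no
second-stage re-estimation of k: the external implementation used in the
source work leaves its second stage unspecified, and the plain SVD fit is
exactly testable. Forecasts launch from observed jump-off rates, avoiding
jump-off bias.

`fit_li_lee()`/`forecast_li_lee()` implement the coherent variant: common
factor = Lee-Carter on the weighted-mean log surface (equal weights by
default; exposure-proportional on request), per-population residual factors
with AR(1) coefficients estimated by least squares and clamped to
[0, 0.98] — strictly below one, which is what bounds long-run divergence.
Degenerate residuals (identical populations) yield k_i ≡ 0 rather than an
arbitrary SVD direction.

## Life-table conventions

q(x) = m/(1 + (1−a)m) for closed intervals with a = 0.5 in the interior
and a0 = 0.1 in the first interval (infant deaths cluster early); the open
interval is closed deterministically with q = 1, L = l/m, e = 1/m rather
than with an extrapolated schedule. The source work does not state its
conventions, so observed-e0 comparisons against published values inherit
this ambiguity; with constant hazard and a = 0.5 everywhere the closed form
e0 = 1/μ holds to 1e-9, which the tests use as an anchor.

## The synthetic world

`generate_scenario()` specifies truth in ρ-space and cumulates it, so the
trend model's estimand is known exactly. Defaults: ages 0–110 (110 open),
60 years from 1950, baseline m(x) = 3e-4 + 3e-5·e^{0.105x} +
0.02·e^{−0.45x} (the infant term reaches the background level around age
10, as in observed national schedules), improvement field
1 % + 2.5 %·exp(−(x − p(t))²/(2·25²)) with the peak age p(t) drifting
40 → 70 over the window, exposure 1e5 person-years per age (HMD-country
scale; 1e6–1e7 for low-noise tests), Poisson death counts with zero counts
replaced by 0.5 so observed rates stay positive.

Presets add regime shocks to ρ: *stagnation-recovery* subtracts the peak
improvement in years 16–45 and adds +1.5 in years 46–60 (a trend reversal
about five years after a political rupture, at all ages);
*crisis-recovery* subtracts 3.5 at all ages plus another 4 at working ages
15–60 in years 41–50, then adds +2 in the recovery decade — a crisis that
halts progress everywhere and reverses it hardest at working ages, which
is what actually depresses period e0. Reference populations experience the
same latent field `lag` = 10 years earlier (attenuation 1.0, baseline
level factor 1.15), which is what makes them informative about reversals
the target has not completed.

What the generator does **not** emulate: migration, cohort effects,
cause-of-death structure, overdispersion beyond Poisson, and vintage
revisions of real data. A green test on this world therefore establishes
that the estimators recover a known ρ-field under Poisson noise and that
the claimed comparative advantages hold there — not that any specific
published national forecast is reproduced. Published headline numbers
(observed e0 values, retrospective MAE magnitudes, forecast medians) depend
on proprietary data vintages and unpublished model internals; the only
published quantities checked exactly are the arithmetic relations inside
the printed forecast-quantile table (interval widths and gains, rounded
half-away-from-zero to whole years as quoted in prose).

## Numerical choices

- P-spline inner products use the GLAM identity (row-tensor products), so a
  111 × 60 Poisson smooth with ~390 coefficients costs milliseconds per
  IRLS step; IRLS starts at crude log rates and stops on a 1e-9 relative
  deviance change.
- Band classification ties: ρ = ±0.5 is *stagnating*, ρ = 4 is *moderate*
  (strong requires strictly more than 4 %).
- Lee-Carter on an exactly constant surface raises `degenerate_fit_error`
  (rank-0 centered matrix); a first singular vector summing to zero is
  likewise rejected as unidentifiable.
- Improvement rates use 100·(1 − ratio), not −100·Δlog m: the band
  thresholds are quoted in percent of the rate ratio. The two definitions
  agree to first order.
- All failures are typed conditions (`parse_error`, `missing_data_error`,
  `alignment_error`, `degenerate_fit_error`, ...) so the evaluation harness
  can record a failing model as an `error:<type>` row — mirroring published
  retrospective comparisons in which some models "generated an error
  message" — without aborting the remaining models.
- Scoring uses the predictive *median* (published forecast tables report
  medians); MAE is the unweighted mean of |forecast − observed| over the
  scored years, with overestimation positive.

## Known limitations

- The linear age-trend is a first-order description of ρ(x,t); strongly
  curved improvement histories (e.g. an improvement peak that accelerates)
  bias long-horizon extrapolations, and the intervals only partially absorb
  that bias.
- The reference blend is additive in trend space with a fixed w(h) path;
  whether the original model blends additively or multiplicatively is not
  stated in the source work, and no data-driven estimate of w_max or τ is
  attempted.
- The bootstrap is the default uncertainty engine; a posterior-sampling
  backend would be a drop-in replacement behind the same draw interface but
  is not implemented.
- No cohort dimension: all smoothing, trends and forecasts are
  period-based.
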