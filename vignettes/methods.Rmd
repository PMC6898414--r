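---
title: "Within-season weather effects on maize yields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-season weather effects on maize yields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropbma)
```

## The problem

County-level maize yields respond nonlinearly to temperature: moderate
thermal accumulation helps the crop, extreme heat hurts it, and the
damage depends on when in the growing season the heat arrives and on how
much water is available. `cropbma` estimates these responses from a panel
of annual county log yields and daily weather, compares specifications
that aggregate weather over the whole growing season against
specifications that keep month-by-month variation, and uses closed-form
Bayesian model comparison to handle the large regressor space the monthly
specifications create.

## Weather features: single-sine degree days

Daily exposure is summarised by growing degree days (GDD) and heating
degree days (HDD). Within a day the temperature course is modelled as one
symmetric sine wave through the daily minimum and maximum (`tmin`,
`tmax`); GDD integrates `max(0, min(T, 29) - 10)` over the day and HDD
integrates `max(0, T - 29)`, in degrees C. The base 10 / cap 29
thresholds are the standard maize values and are configurable through
`degree_day_thresholds()`. Among the several degree-day conventions in
use, the package fixes:

* **single sine**, not double-sine or hourly interpolation: one min/max
  pair per day defines the curve, and consecutive days are integrated
  independently (no cross-midnight smoothing);
* **horizontal cutoff** at the cap: hours above 29 degrees C accrue GDD
  at the cap rate, while their excess above the cap accrues HDD;
* a day with `tmin == tmax` is a constant-temperature day, the analytic
  limit of the sine.

The closed form (a Baskerville–Emin arcsine expression) is checked in the
test suite against dense trapezoid quadrature of the sine curve to 1e-6,
and continuity at every threshold crossing is probed by finite
differences. Monthly features are sums over complete Gregorian calendar
months; a missing day is an error, never a silent truncation.

## The four specifications

All specifications model `log yield` for county *i*, year *t* with county
fixed effects and state-specific quadratic time trends always included:

| Spec | Weather columns | Count |
|------|-----------------|-------|
| M1 | seasonal (Apr–Oct) sums: GDD, HDD, Prec, Prec² | 4 |
| M2 | M1 + GDD×Prec, GDD×Prec², HDD×Prec, HDD×Prec² (seasonal) | 8 |
| M3 | monthly GDD, HDD, Prec, Prec² for each of Apr–Oct | 28 |
| M4 | M3 + the four interaction families by month | 56 |

Seasonal `Prec²` is the square of the seasonal sum (not the sum of
monthly squares); monthly `Prec²` is squared month-wise; interaction
columns are elementwise products of the corresponding columns. The fixed
part `Z` holds per-state `Time` and `Time²` columns (`Time = year -
first_year + 1`) plus one indicator column per county and no global
intercept, so `Z` has full column rank and the marginal-likelihood
formula below can operate on the literal column block `(X_γ, Z)`.

## Bayesian model comparison

Let `γ` flag a subset of the 56 weather columns of M4. With the reference
prior on coefficients and error variance, the integrated likelihood has
the closed form

```
m(data | γ) = Γ((n − p_γ)/2) |W_γ' W_γ|^(−1/2) [π RSS_γ]^(−(n−p_γ)/2)
```

with `W_γ = (X_γ, Z)`, `p_γ = ncol(W_γ)` and `RSS_γ` the residual sum of
squares after projecting `y` off `W_γ`'s column space. Under a uniform
prior over all `2^56` subsets the prior cancels from every ratio, so
posterior model probabilities are a softmax of the log marginals. The
trend and fixed-effect columns are never subject to selection.
Implementation notes:

* everything is computed in log space via QR decompositions; `Z` is
  factored once per design and selected columns are residualised against
  it, so the determinant splits and the n×n projector is never formed;
* rank decisions use a relative tolerance of 1e-10 on QR diagonal
  factors; a rank-deficient proposal is rejected, not fatal;
* no strong-heredity constraint: interactions may enter without their
  main effects, as the uniform prior implies (`heredity` filtering can be
  imposed downstream by the user but is not built in).

**Column scaling.** The formula is not invariant to rescaling the columns
of `X`: the determinant term subtracts the log column norms, which acts
as a units-dependent prior on model size. In natural units this matters
concretely — April or October HDD is a near-zero column (most years have
no hours above 29 degrees C in those months), and a near-zero column
*raises* the marginal likelihood of any model that includes it, so
selection in natural units systematically drags in physically empty
regressors. `build_design()` therefore standardizes the weather columns
to unit sample SD by default before model comparison, and every reported
coefficient, credible interval, marginal effect and warming impact is
converted back to natural units (per degree day, per mm), so the scaling
affects only the model-space ranking. `standardize = FALSE` restores
literal natural-unit columns for comparison.

### Search and averaging

The model space is explored by Markov chain Monte Carlo model composition
(`mc3_search()`): a Metropolis random walk that flips one uniformly
chosen indicator per iteration and accepts with probability
`min(1, exp(Δ log m))`. Defaults are 20,000 iterations with 2,000
burn-in, a single chain, and a mandatory seed; every evaluated model is
cached by its indicator bitstring. Bayesian variable selection (BVS)
takes the highest-marginal-likelihood visited model (`select_best()`,
ties broken toward fewer variables then lexicographically); Bayesian
model averaging (BMA) keeps the Occam's window of visited models within a
factor `c = 3` of the best and renormalizes their weights
(`occams_window()`). On spaces small enough to enumerate,
`enumerate_models()` provides the exact counterpart, and the test suite
checks MC3 visit frequencies against exhaustive posteriors using
batch-means Monte-Carlo standard errors.

Within each retained model the coefficient posterior is multivariate t:
centered at the least-squares estimate with scale
`s²(W_γ'W_γ)^{-1}` and `n − p_γ` degrees of freedom; weather variables
outside the model are exactly zero. Mixture summaries over the window use
10,000 seeded Monte-Carlo draws by default; a single-model window uses
analytic t quantiles. Credible intervals are conditional on the window:
they do not account for truth lying outside every retained model, which
is visible in the package's own recovery simulations as coverage slightly
below nominal when a weak coefficient is absorbed by a correlated proxy.

## Out-of-sample evaluation

`cross_validate()` performs k-fold cross-validation with whole years as
blocks (`make_year_folds()`): years are permuted under a seed and dealt
round-robin, so 37 years in 10 folds always gives seven 4-year and three
3-year blocks, and no county-year of a test year ever informs its own
prediction. Reported measures are RMSE, MAPE, Pearson correlation and the
skill score `−(MSE_m − MSE_benchmark)/MSE_benchmark` with the seasonal
M1-OLS model as benchmark. Two documented choices:

* the skill score is computed per fold against the benchmark's same-fold
  MSE and then averaged, which is why a specification's averaged skill is
  not algebraically recoverable from its averaged RMSE;
* MAPE is computed on the model's response scale — log yields — since
  predictions are log-yield predictions; MAPE on level yields would
  differ.

Within cross-validation the MC3 chain defaults to 2,000 iterations per
fold for runtime; this is configurable and the package's acceptance
script states the settings it uses.

## Warming scenarios and conditional effects

A uniform warming scenario adds a constant to every daily `tmin` and
`tmax` (precipitation unchanged) and re-derives monthly degree days, so
the nonlinear HDD response to warming emerges from the within-day sine
integral rather than from shifting monthly totals. Because the fixed part
`Z` is identical under both weather sets it cancels exactly, and the
impact per county-year is the weather-column difference times the
coefficients. The overall impact averages all county-years with counties
equally weighted (no production weighting). Intervals are 95% by default:
posterior-draw quantiles for BVS/BMA fits (including between-model
variance), delta-method normal intervals for OLS.

Conditional marginal effects evaluate
`∂ log yield / ∂ DD_m = b_main + b_×Prec · P + b_×Prec² · P²` at the
25th and 75th percentiles of the fitting sample's monthly precipitation,
pooled across counties and years (pooling is a documented choice; the
percentile uses the linear-interpolation definition, R's type 7).
Variables absent from every window model contribute exactly zero.

## The synthetic panel generator

No public fixture reproduces the restricted county yield/weather panels
this kind of analysis runs on, so the package ships a seeded generator
(`generate_weather()`, `generate_panel()`) that emulates their
statistical structure and exports the ground truth for recovery tests.
Daily weather per county: an annual sinusoid in daily mean temperature
(level 10 °C, amplitude 14 °C, peak at day 200 — Corn-Belt-like), a
once-drawn county offset (SD 1.5 °C, the latitude proxy), a constant
diurnal range (10 °C) shared by tmin and tmax, and stationary AR(1) noise
(SD 3 °C, autocorrelation 0.6). Monthly precipitation is gamma(shape 4,
scale 22 mm) split equally over the month's days — only monthly totals
matter downstream. The panel is balanced by default; whether the real
panels are exactly balanced is not knowable from their public summaries,
and the assumption is recorded here.

Log yields follow the M4 structure: county fixed effects (SD 0.2),
a common state trend (1.5%/year with mild curvature), a sparse
coefficient vector on the 56 weather columns, and Gaussian noise.
The default truth activates `GDD_5 (+1.6e-3)`, `GDD_6 (+1.4e-3)`,
`HDD_7 (−1.0e-2)`, `HDD_8 (−1.4e-2)` and `Prec_7 (+2e-3)` with noise SD
0.10. The signs and rough magnitudes follow the crop-econometrics
literature (beneficial spring/early-summer warmth, harmful mid-summer
heat, beneficial July rain); the magnitudes sit at the upper end of that
range because the M4 column space contains near-collinear pairs — July
GDD is nearly constant across county-years, so `Prec_7` and
`GDD×Prec_7` correlate at ~0.99 — and exact support recovery at the
reference panel size (15 counties × 37 years) requires partial
t-statistics around 5. That choice is part of the study conditions, made
once from this power reasoning.

What the generator does *not* emulate: spatial correlation of weather
across counties, crop calendars, irrigation, technology shocks, or
unbalanced reporting. Passing recovery tests on this generator shows the
estimation machinery is correct under the model's own assumptions; it
does not certify behaviour under real-data misspecification.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data
at deliberately modest sizes chosen as representative rather than
exhaustive: the reference panel is 3 states × 5 counties × 37 years
(555 county-years, the scale at which all 56 M4 columns plus 21 fixed
columns remain comfortably estimable), enumeration checks use 8–10
variable spaces, MC3 chains of 1,500–10,000 iterations are used inside
replicated simulations, and 50,000 iterations where a chain is compared
against an exhaustive posterior.

## Known limitations

* The marginal likelihood's scale sensitivity is handled by
  standardization, not solved; a scale-invariant prior (e.g. a g-prior)
  is out of scope.
* Credible intervals are conditional on the retained window (see above).
* Counties are equally weighted in scenario averages; production
  weighting would change the headline impact numbers.
* MAPE on log yields is small by construction (log yields are ~4–5);
  comparisons should rely on RMSE/skill, which is how the package's own
  summaries are organised.
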