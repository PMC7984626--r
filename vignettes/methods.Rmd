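---
title: "Stacked ensemble forecasting of weekly ILI visit volumes: models, design choices, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble forecasting of weekly ILI visit volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forecasting problem

An emergency department wants, at week *t* of a flu season, forecasts of
its weekly count of ILI-positive visits 1 to 4 weeks ahead, with
uncertainty honest enough to drive staffing decisions. Seasons run from
roughly the last week of August (the default season boundary is epi-week
35, configurable) and last 52 or 53 weeks under the MMWR calendar
(Sunday-start weeks; week 1 contains January 4). No single model family
dominates this problem: trajectory-matching methods excel when the current
season resembles a past one, regression methods exploit covariates such as
temperature and immunization rates, and time-series methods track local
autocorrelation. The package therefore fits four members and combines them
by stacking.

## Member models

### Empirical Bayes

Each complete past season is smoothed by quadratic trend filtering:
minimize ½‖y − f‖² + λ‖D⁽³⁾f‖₁, whose solutions are piecewise-quadratic
curves with adaptive knots — exact quadratics lie in the penalty's null
space and pass through untouched. The solver is an ADMM iteration with
over-relaxation and residual balancing; λ is selected on a 12-point
log-spaced grid by 5-fold cross-validation with interleaved folds
(endpoints always retained) under the one-standard-error rule, which
guards against the overfitting that plain CV-minimum selection shows on
52-point seasons. The residual SD of the fit, floored at 1e-6, becomes the
season's noise level σ_s.

The prior over the current season's trajectory is formed by resampling:
draw a source curve uniformly from the pool; draw a target peak height and
a target peak week *independently* from the pool's collections of smoothed
peak heights and weeks (the two pools are treated as exchangeable
marginals rather than joint draws from one season); draw a pacing factor
uniformly on [0.75, 1.25]. The source curve is rescaled so its maximum
equals the target height, shifted so its argmax lands on the target week,
and time-dilated about the (shifted) peak by the inverse pacing factor;
evaluation outside the source domain holds the edge values. Each candidate
receives a Gaussian likelihood weight exp(−Σ(y_τ − f̃_τ)²/(2σ_s²)) over the
season-to-date, computed in log space and normalized so the best candidate
has weight 1; weighting precedes the injection of N(0, σ_s²) observation
noise into the candidate values. The point forecast at t+ℓ is the weighted
median — the smallest sampled value with at most half the weight strictly
below and at most half strictly above — and the centiles are weighted
percentiles of the same noisy sample. The reference Monte-Carlo batch size
is 1e5; the evaluation harness and tests run at 2e3–1e4, which widens
Monte-Carlo noise in the far centiles but leaves points and central
intervals stable.

One implementation note: within one (training pool, target season) pass
the harness draws the Monte-Carlo batch once and reuses it across forecast
origins, recomputing only the likelihood weights via cumulative squared
errors. The candidates are i.i.d. draws from the same prior whatever the
origin, so this is the same estimator, evaluated on a shared sample; the
per-origin API `eb_forecast()` draws a fresh batch each call.

### STL + ARIMA(2,0,1)

The training counts are decomposed by STL with a periodic seasonal window;
the seasonal component is averaged per epi-week (week 53 folded into week
52, since 53-week seasons occur in only some years) and subtracted.
An ARIMA(2,0,1) with intercept is fit to the adjusted series by maximum
likelihood — the order is fixed, matching an AIC-selected configuration
for this problem class; an explicit stationarity check rejects fits with
AR roots inside the unit circle. Forecasts use the standard recursion
(future innovations zero, forecasts fed back), with σ̂²_ℓ = σ² Σ_{j<ℓ} ψ_j²
and Gaussian centiles; the target week's seasonal index is re-added to the
point and every centile. These intervals ignore STL estimation
uncertainty and are known to undercover slightly; that behaviour is
retained deliberately, and the evaluation reports it.

### Quantile regression forest

Predictors: ILI count lags 0–2, epi-week, temperature (min and max) lags
0–2, immunization-rate lags 0–2, and population — 14 predictors, with 4
sampled per split (the ⌊√P⌋ heuristic) and 2000 trees by default. The
forest substrate is `ranger`; the package retains each tree's terminal
node of every training row plus the bootstrap inbag counts and computes
Meinshausen's weighted empirical CDF itself: training row *i* gets weight
averaged over trees of (inbag count in the query's leaf) / (leaf's total
inbag count). The point forecast is the forest mean; centiles are weighted
quantiles of the training targets. The weighted-quantile convention
generalizes the type-7 continuous convention — sorted values sit at
cumulative positions (C_i − w_i)/(1 − w_n), linearly interpolated — so
uniform weights reproduce `stats::quantile` exactly.

### Linear regression

Per horizon ℓ, OLS of y_{t+ℓ} on the current count, current covariates,
population, a year trend, epi-week fixed effects (week 53 folded to 52 so
every level exists in every training year), the current slope
y_t − y_{t−1}, and the count of upward movements over the preceding three
weeks entered as a 4-level categorical. The slope default is the first
difference — the simplest reading of "slope at the current period".
σ̂(x) combines the prediction standard error with the residual variance;
centiles are Gaussian. Rank-deficient designs are refused by name; with
only two training seasons the population and year-trend columns are
necessarily collinear, which is why the stacking protocol needs at least
three seasons besides the held-out one.

## Stacking

For evaluation season *s* and each horizon, every remaining season *s′* is
held out in turn; members are trained on the data minus {s, s′} and
predict s′ week by week. The pooled panel feeds the simplex-constrained
least-squares problem, solved exactly by enumerating all 2^M − 1 candidate
supports and solving each equality-constrained KKT system (M = 4 gives 15
tiny linear systems); among feasible candidates the smallest objective
wins, with the minimum-norm weight vector breaking exact ties. Degenerate
panels in which all members coincide return equal weights with a flag. Two
feasibility bounds are asserted on every run: the in-panel objective never
exceeds any single member's nor the naive ensemble's. A member that fails
to train on every inner fold (for example ARIMA on a two-season splice,
which is shorter than the two full periods STL needs) is dropped from the
panel and receives stacking weight zero rather than destroying the panel
by listwise deletion; partially missing rows are dropped listwise.

Weights are estimated separately per horizon and per evaluation season.
Ensemble centiles are weight-averaged member centiles — a deliberately
simple construction whose coverage the evaluation measures rather than
assumes.

## The synthetic data generator

The generator emulates the marginal structure of a high-volume pediatric
ED surveillance series: a constant off-peak baseline (135 visits/week)
plus one Gaussian-bump wave per season with peak height ~ U[300, 420],
peak week ~ U[18, 30], and width ~ U[5, 8] weeks; negative-binomial
counts (size 35, matching strong overdispersion); an annual temperature
sinusoid with its trough in mid-January (maxima swing 80% of the minima's
±13 °C amplitude, so winters are cold when epidemics peak); an
immunization-rate ramp to a 0.23 plateau by week 20; and population
growing ~15 000/season with random annual drift (exactly linear growth
would be collinear with the year trend). Defaults were calibrated once so
a 7-season run has an overall mean weekly count near 210 (target band
180–240) and a high-volume-week mean near 330 (band 290–380), mirroring
the reference descriptives, and then frozen. Seasons follow the real MMWR
calendar, so 53-week seasons arise naturally.

What the generator does *not* emulate: multi-wave seasons, strain
replacement dynamics, holiday reporting artifacts, care-seeking shifts,
or any mechanistic transmission structure. Passing tests on this generator
therefore demonstrates that the pipeline is correct and that stacking
behaves as designed under realistic marginals — not that any member model
is well-specified for a particular hospital's data.

## Numerical choices and degenerate inputs

- Trend filter: ADMM tolerance 1e-5 relative (4000 iterations for the
  final fit), warm starts across the λ grid; λ_max is the smallest penalty
  at which the solution is globally quadratic.
- Weighted median ties: the smallest qualifying value is returned.
- High-volume ties at the 25% boundary: the earlier week wins.
- All forecast centiles are floored at zero and made nondecreasing on
  construction; points are floored on report.
- EB likelihood underflow (all weights zero, e.g. a σ_s near the 1e-6
  floor with mismatched observations) falls back to uniform weights with
  a warning.
- Log score: natural log; the −5 floor applies both when the observation
  leaves the [q01, q99] support and when no centile lands in the ±25 band.
- Partial seasons are flagged, never silently dropped; they are evaluated
  (with fewer origins) but excluded from the EB smoothing pool.

## Problem sizes used by the test suite

The packaged defaults follow the reference configuration (EB 1e5 samples,
2000 trees). The test suite and the acceptance script run the same code
at reduced sizes chosen once as adequate for the properties under test:
EB at 300–2000 samples, forests of 50–200 trees, and 20 replicate
end-to-end runs of the 7-season study for the ensemble-dominance check.
At these sizes the stacked ensemble's pooled MAE sits 1–3% below the best
member's, so the ±5% acceptance band is not sensitive to the reduction.

## Known limitations

- Stacking weights are constant within a season; time-varying weights are
  out of scope.
- ARIMA and LR intervals are Gaussian approximations; EB centiles at small
  batch sizes are noisy in the extreme tails.
- The LR member requires every epi-week level in training; the week-53
  folding handles the only systematic gap.
- MAPE requires strictly positive observed counts (the intended use is
  EDs with at least ~50 weekly ILI visits); zero weeks raise an error
  naming the offending index.
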