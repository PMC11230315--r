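---
title: "Ensemble methods for forecast hubs: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble methods for forecast hubs: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubpool)
```

## The setting

Collaborative forecast hubs collect probabilistic predictions from many
independent models in a common tabular format: one prediction per row,
identified by a model id, a set of *task ID* columns (what is being
predicted: location, reference date, horizon, target), an *output type*
(`mean`, `median`, `quantile`, `cdf`, `pmf`, or `sample`), an
*output type id* (the quantile level $\theta$, the evaluation point $x$,
the category, or the sample index), and a numeric value. hubpool
validates this format, combines predictions across models, scores the
result against observations, and simulates whole hubs with known ground
truth.

## The two ensembling families

Write $F_i$ for model $i$'s predictive CDF, $F_i^{-1}$ for its quantile
function, and $w_i \ge 0$, $\sum_i w_i = 1$ for model weights.

**Quantile (Vincent) average** — `simple_ensemble()` with the default
mean aggregation averages *values at fixed probability levels*:
$$F_Q^{-1}(\theta) = \sum_{i=1}^N w_i F_i^{-1}(\theta).$$
For location–scale families this returns the same family with averaged
location and scale: averaging normal components
$N(\mu_i, \sigma_i)$ yields exactly
$N(\sum w_i \mu_i,\; \sum w_i \sigma_i)$, which is what the package's
closed-form tests assert to 1e-9. Any other aggregation (median, a
custom function of `x` and `w`) may be substituted; a median of
quantiles is the robust variant widely used for short-term epidemic
forecasting.

**Linear opinion pool (LOP)** — `linear_pool()` averages *probabilities
at fixed values*:
$$F_{LOP}(x) = \sum_{i=1}^N w_i F_i(x),$$
a mixture distribution. Both families share the mean
$\mu = \sum_i w_i\mu_i$, but the LOP keeps between-model spread:
$$\sigma^2_{LOP} = \sum_i w_i \sigma_i^2 +
  \sum_i w_i (\mu_i - \mu_{LOP})^2,$$
so the quantile average's variance never exceeds the LOP's. For `cdf`
and `pmf` inputs the LOP is literally a per-row weighted mean and the
two functions agree bitwise; for `quantile` inputs the LOP must be
approximated (below); `sample` inputs are pooled by stratified
concatenation; `median` has no meaningful LOP and is rejected.

## Reconstructing a distribution from quantiles

Quantile submissions give $F_i^{-1}$ at a fixed level grid (by default
the 23 FluSight levels $\{0.01, 0.025, 0.05, 0.10, \dots, 0.90, 0.95,
0.975, 0.99\}$), but the LOP needs $F_i(x)$ at common values.
`fit_quantile_distribution()` therefore rebuilds each component:

* **Interior**: a shape-preserving monotone cubic Hermite spline
  (Fritsch–Carlson, `stats::splinefun(method = "monoH.FC")`)
  interpolates $\theta$ as a function of the value. Interpolating in
  this direction (CDF domain) keeps the implied density nonnegative;
  the spline direction is a design choice the format itself does not
  fix.
* **Tails**: below the smallest and above the largest submitted value,
  a location–scale family (`norm` default, `lnorm`, `cauchy`) is
  matched exactly to the two most extreme (level, value) pairs on that
  side. Lognormal matching happens in log space and requires positive
  values; an infeasible request errors rather than silently switching
  family, because a silent fallback would hide a modeling mistake.
* **Ties**: distinct levels mapped to one value (a flat CDF stretch)
  collapse to a single node at the mean of their levels, with a
  warning; fewer than two distinct nodes is an error.

The quantile function inverts the spline by vectorized bisection
(absolute tolerance 1e-10 on the probability scale); tails invert in
closed form. `quasi_random_samples(dist, n)` returns
$F^{-1}\!\big((k - 0.5)/n\big)$ for $k = 1..n$ — a deterministic
midpoint grid rather than Monte Carlo draws, chosen because it is
endpoint-free, symmetric, and removes all sampling noise from
downstream checks.

The quantile-LOP then: (1) fits each component, (2) draws each model a
weight-proportional share (largest-remainder allocation) of
`n_samples * n_models` quasi-random samples, (3) pools them and reads
the ensemble quantiles at exactly the input level grid. Quantile
extraction uses the **type-5** order-statistic convention — the exact
inverse of the midpoint empirical CDF — so a pool of identical
components reproduces its inputs up to local interpolation error. We
measured both conventions on a $N(100, 10)$ component at
`n_samples = 1e4`: type 5 errs by at most 3.3e-3 (at level 0.01, where
the quantile function's curvature between adjacent midpoint samples is
largest; at most 1e-5 for levels in $[0.025, 0.975]$), type 7 by
1.2e-2. The error shrinks like $n^{-2}$. This is why the package's
single-model reproduction tests assert 1e-4/5e-3-scale bounds rather
than exact recovery: the sample-then-extract algorithm is intrinsically
approximate at the outermost levels, and no order-statistic
interpolation can do better than the curvature term
$\left|\,(F^{-1})''(\theta)\,\right|/(8 n^2)$.

All models within a task group must submit the same level grid; the
package errors on mismatches rather than re-interpolating onto a union
grid, mirroring the complete-cases regime under which hub analyses are
run (a model silently missing one level would otherwise shift a single
quantile of the ensemble).

## Sample pooling and compound task IDs

`sample` predictions may be draws from a *joint* distribution: rows
sharing an index form one draw across, say, all four horizons. The
*compound task ID set* names the task IDs that identify one modeled
unit (the joint distribution does not capture dependence across them);
*derived task IDs* (e.g. target date = reference date + horizon) are
functions of other columns. `pool_samples()` concatenates all samples
(equally weighted only — weighted sample pools are deliberately
unsupported) and re-indexes them densely. When a subset of
`n_output_samples` is requested, each of the $N$ models contributes
$\lfloor n/N \rfloor$ indices plus a largest-remainder share (ties by
model id order, so 3 models and $n = 100$ give 34/33/33), indices are
drawn uniformly without replacement under an explicit seed, and an
index's rows always travel together, preserving the joint structure.
`validate_compound_taskids()` guards this: every index must span the
full cross-product of the free task IDs, and derived columns must be
functionally determined.

## Scoring

`score_forecasts()` evaluates quantile forecasts against a target
series. With $K$ central intervals (nominal coverage $1 - \alpha_k$,
bounds $l_k, u_k$) and median $m$:
$$\mathrm{WIS} = \frac{1}{K + 1/2}\left(\frac{|y - m|}{2} +
  \sum_{k} \frac{\alpha_k}{2}\, IS_{\alpha_k}(l_k, u_k, y)\right),
\qquad
IS_\alpha = (u - l) + \tfrac{2}{\alpha}(l - y)_+ +
  \tfrac{2}{\alpha}(y - u)_+ .$$
The package accumulates the width terms as *dispersion* and the
penalty terms (plus the median term, split by sign) as *over-* and
*under-prediction*, so the decomposition sums to the WIS by
construction; with the grid $\{0.5\}$ the score reduces exactly to the
absolute error of the median. Interval coverage uses closed intervals
(a boundary observation counts as covered — rare for continuous
targets, but the convention must be deterministic). Relative metrics
(rWIS, rMAE) are ratios of mean scores over the task intersection with
a named baseline, which scores exactly 1 against itself; any stratum
exclusions (e.g. dropping a national-level location) are the caller's
filtering responsibility.

## The synthetic hub generator

`hub_spec()` + `generate_component_outputs()` /
`generate_target_series()` emulate a miniature hub in which every
component model *is* a known parametric distribution (normal,
lognormal, or point mass; parameters scalar or per-task), so every
pipeline has closed-form ground truth: quantile rows are exact
quantiles, cdf/pmf rows exact probabilities, mean/median rows exact
moments, samples seeded inverse-CDF draws. Joint samples share one
uniform per index across the `joint_across` task IDs, creating genuine
cross-horizon dependence (comonotone draws) so compound-task-ID
validation is exercised by construction. Observations come from a
designated truth distribution under `seed + 1`, keeping forecast and
observation streams independent.

Defaults mirror the conditions the ensembling literature works under:
the 23-level FluSight grid; two-to-three component hubs with
$N(100, 10)$ and $N(120, 5)$-style separation (mixture mean 110,
mixture variance $\tfrac12(10^2 + 5^2) + \tfrac12(10^2 + 10^2) =
162.5$); 1e4 quasi-samples per model (1e5 in the moment-identity
checks); 100 samples per model for pooling; 2000 tasks for coverage
calibration, where the binomial $3\sigma$ band around 0.95 is
$\pm 0.0146$.

What the generator does **not** emulate: epidemic dynamics (components
are distributions, not mechanistic models), model misspecification and
miscalibration patterns of real teams, missing submissions, revisions,
or count-valued/truncated-at-zero targets. A green test therefore
establishes the *algebra* of the methods — identities, allocations,
decompositions, calibration under a correctly specified forecaster —
not their epidemiological performance; conclusions like "the median
ensemble scores best on real influenza data" are outside what this
package's tests can or do claim.

## Numerical choices, in one place

* PMF groups must sum to 1 within 1e-6 (printed example tables round to
  three decimals, so far looser data still validate); CDF monotonicity
  is strict after rounding values to 12 digits.
* `output_type_id` is dual-typed: numeric for quantile levels and
  numeric cdf points, string otherwise; grouping and canonical sorting
  use the number rendered at 10 significant digits, and PMF categories
  sort by a declared ordinal vocabulary when one is given (else
  lexicographically).
* Duplicate (model, task, type, id) rows are rejected, not deduplicated
  — a duplicated submission is more likely a pipeline error than an
  intentional repeat.
* Weights are nonnegative, normalized per stratum, and must cover every
  model exactly once per stratum; an all-zero stratum errors. Equal
  explicit weights produce bitwise-identical output to no weights.
* Incomplete groups (a model present at some output type ids of a task
  but not others) error by default; `partial = "renormalize"` opts into
  averaging whoever is present with renormalized weights.
* Bisection tolerances: 1e-10 (probability scale) for quantile
  inversion; CSV writes at 15 significant digits so round trips are
  value-stable.

## Known limitations

Weighted sample pooling, beta-transformed or trained-weight pools,
trimming, scoring of cdf/pmf/sample types (log score, CRPS), and
re-interpolation across mismatched quantile grids are deliberately out
of scope. Tail reconstruction can only be as good as the two extreme
quantiles it is matched to; Cauchy tails with very close extreme pairs
produce heavy extrapolations by design. The quantile-LOP is exact only
in the limit `n_samples` $\to \infty$; at the default 1e4 its outermost
levels carry errors of order 1e-3 on hospitalizations-scale values.
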