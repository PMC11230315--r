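# hubpool

Multi-model ensembles and evaluation for probabilistic forecast hubs.

Collaborative forecast hubs — the organizational backbone of modern
outbreak forecasting for influenza, COVID-19, dengue and others —
collect predictions from many independent models in a standardized
tabular *model output* format and publish a combined ensemble. hubpool
is a self-contained R toolkit for that workflow, aimed at hub
maintainers and forecast researchers:

* **Schema** — validate and standardize model-output tables (output
  types `mean`, `median`, `quantile`, `cdf`, `pmf`, `sample`), weight
  tables, and target time series, with per-type validity rules.
* **Ensembling** — the two canonical families for combining
  probabilistic forecasts:
  * the **quantile (Vincent) average**,
    `F_Q⁻¹(θ) = Σᵢ wᵢ Fᵢ⁻¹(θ)`, via `simple_ensemble()` (mean, median,
    or custom aggregation; optional weights);
  * the **linear opinion pool** (mixture),
    `F_LOP(x) = Σᵢ wᵢ Fᵢ(x)`, via `linear_pool()` — including the
    reconstruction path for quantile submissions (monotone cubic spline
    interior, normal/lognormal/Cauchy tails, deterministic quasi-random
    sampling) and stratified pooling of joint `sample` submissions with
    compound-task-ID validation.
* **Evaluation** — weighted interval score (WIS) with its exact
  dispersion/over/under-prediction decomposition, MAE of the median,
  50%/95% interval coverage, and relative skill (rWIS, rMAE) versus a
  baseline model.
* **Synthetic hubs** — `hub_spec()` and `generate_component_outputs()`
  build miniature hubs whose component models are known parametric
  distributions, so every ensembling and scoring path can be tested
  against closed-form ground truth.
* **CLI** — `validate` / `simulate` / `ensemble` / `score` subcommands
  over CSV files (`inst/cli/hubpool`).

The two families differ in a way that matters for interpretation: both
share the mean `Σ wᵢ μᵢ`, but the linear pool keeps between-model
spread (`σ²_LOP = Σ wᵢ σᵢ² + Σ wᵢ (μᵢ − μ_LOP)²`) while the quantile
average cancels it, so its variance is never larger. See
`vignettes/ensemble-methods.Rmd` for the full methodology, numerical
choices, and limits.

## Worked example

Three models forecast the probability that weekly flu-hospitalization
intensity falls in each of four ordered categories; the equally
weighted mean ensemble is their linear pool:

```r
library(hubpool)

cats <- c("low", "moderate", "high", "very high")
pmf <- data.frame(
  model_id = rep(c("Flusight-baseline", "MOBS-GLEAM_FLUH", "PSI-DICE"),
                 each = 4),
  target = "wk flu hosp rate category", horizon = 1,
  output_type = "pmf", output_type_id = rep(cats, 3),
  value = c(0.000, 0.003, 0.073, 0.924,
            0.000, 0.002, 0.163, 0.835,
            0.013, 0.065, 0.218, 0.704))
tbl <- validate_model_output(pmf, c("target", "horizon"),
                             pmf_category_order = cats)
simple_ensemble(tbl, model_id = "simple-ensemble-mean")
#>              model_id                    target horizon output_type
#>  simple-ensemble-mean wk flu hosp rate category       1         pmf
#>  simple-ensemble-mean wk flu hosp rate category       1         pmf
#>  simple-ensemble-mean wk flu hosp rate category       1         pmf
#>  simple-ensemble-mean wk flu hosp rate category       1         pmf
#>  output_type_id       value
#>             low 0.004333333
#>        moderate 0.023333333
#>            high 0.151333333
#>       very high 0.821000000
```

The ensemble forecasts an 82% chance of "very high" intensity — the
average of the three component probabilities per category, summing to 1
by construction.

For quantile forecasts the two families genuinely differ. On a
synthetic two-model hub (N(100, 10) and N(120, 5)):

```r
hub <- hub_spec(
  models = list(list(model_id = "A", family = "norm", mu = 100, sigma = 10),
                list(model_id = "B", family = "norm", mu = 120, sigma = 5)),
  task_grid = list(location = "MA", horizon = 0),
  truth = list(family = "norm", mu = 110, sigma = 8), seed = 42)
q  <- generate_component_outputs(hub, "quantile")
qa <- simple_ensemble(q, model_id = "quantile-average")
lp <- linear_pool(q, n_samples = 1e5, model_id = "linear-pool")
#>  level quantile_average linear_pool
#>   0.05             97.7        87.2
#>   0.25            104.9       100.0
#>    0.5            110.0       113.3
#>   0.75            115.1       120.3
#>   0.95            122.3       126.5
```

Both are centered near the mixture mean 110, but the linear pool's
intervals are visibly wider (90% interval ≈ [87, 127] vs [98, 122]):
it retains the disagreement between the two components as forecast
uncertainty. Scoring both against an observation drawn from the truth
distribution:

```r
tg <- generate_target_series(hub)
sc <- score_forecasts(validate_model_output(
  rbind(as.data.frame(qa), as.data.frame(lp)), c("location", "horizon")), tg)
summarize_scores(sc, baseline_model_id = "quantile-average")
#>          model_id  wis  mae cov50 cov95 rwis rmae
#>  quantile-average 1.61 0.30     1     1 1.00  1.0
#>       linear-pool 3.37 3.63     1     1 2.09 12.1
```

Here the narrower quantile average wins on WIS (rwis of the linear pool
is 2.09 > 1, i.e. worse than baseline) while both intervals cover the
observation — on a single task this is anecdote, not evidence; the test
suite makes the systematic claims.

## Command line

```sh
Rscript inst/cli/hubpool simulate --spec spec.json --out-dir hub/
Rscript inst/cli/hubpool ensemble lop --n-samples 10000 \
    --task-ids location,horizon hub/quantiles.csv hub/lop.csv
Rscript inst/cli/hubpool score --targets hub/targets.csv \
    --baseline hub-ensemble --task-ids location,horizon \
    hub/lop.csv hub/scores.csv
```

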