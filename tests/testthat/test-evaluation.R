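# WIS, coverage, and relative metrics.

# Independent oracle: interval-score summation straight from the formula.
wis_oracle <- function(levels, values, y) {
  o <- order(levels)
  levels <- levels[o]
  values <- values[o]
  m <- values[abs(levels - 0.5) < 1e-9]
  low <- which(levels < 0.5 - 1e-9)
  K <- length(low)
  total <- 0.5 * abs(y - m)
  for (i in low) {
    alpha <- 2 * levels[i]
    l <- values[i]
    u <- values[abs(levels - (1 - levels[i])) < 1e-9]
    is_a <- (u - l) +
      (2 / alpha) * (l - y) * (y < l) +
      (2 / alpha) * (y - u) * (y > u)
    total <- total + (alpha / 2) * is_a
  }
  total / (K + 0.5)
}

test_that("wis handles hand-evaluated single-interval cases", {
  # median 5, central 50% interval [0, 10]
  lv <- c(0.25, 0.5, 0.75)
  vals <- c(0, 5, 10)
  inside <- wis(lv, vals, 5)
  expect_equal(inside$overprediction, 0)
  expect_equal(inside$underprediction, 0)
  expect_equal(inside$wis, inside$dispersion)
  expect_equal(inside$dispersion, (0.25 * 10) / 1.5)

  out <- wis(lv, vals, 12)
  # interval penalty (2/0.5)*(12-10) = 8, weighted by alpha/2 = 0.25,
  # plus the median term 0.5*(12-5), all over K + 0.5 = 1.5
  expect_equal(out$overprediction, (0.25 * 8 + 0.5 * 7) / 1.5)
  expect_equal(out$underprediction, 0)
  expect_equal(out$wis, wis_oracle(lv, vals, 12), tolerance = 1e-12)

  # {0.5} grid: WIS degenerates to absolute error, exactly
  expect_identical(wis(0.5, 7, 10)$wis, 3)
  expect_identical(wis(0.5, 7, 7)$wis, 0)
})

test_that("decomposition sums to WIS and matches the oracle on random cases", {
  set.seed(202)
  for (i in 1:200) {
    K <- sample(1:11, 1)
    lows <- sort(runif(K, 0.01, 0.49))
    lv <- c(lows, 0.5, rev(1 - lows))
    vals <- sort(rnorm(length(lv), 0, 10))
    y <- rnorm(1, 0, 15)
    s <- wis(lv, vals, y)
    expect_equal(s$wis,
                 s$overprediction + s$underprediction + s$dispersion,
                 tolerance = 1e-9)
    expect_equal(s$wis, wis_oracle(lv, vals, y), tolerance = 1e-9)
    expect_gte(s$wis, 0)
  }
})

test_that("widening an interval to include y cannot increase WIS", {
  lv <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  vals <- c(-3, -1, 0, 1, 3)
  y <- 4                       # outside the 80% interval
  before <- wis(lv, vals, y)$wis
  wider <- vals
  wider[5] <- 4                # upper 0.9 quantile stretched to y
  expect_lte(wis(lv, wider, y)$wis, before)
})

test_that("asymmetric or median-less grids are rejected", {
  expect_error(wis(c(0.25, 0.5), c(0, 1), 0), class = "hubpool_grid_error")
  expect_error(wis(c(0.25, 0.75), c(0, 1), 0), class = "hubpool_grid_error")
  expect_error(pi_coverage(c(0.25, 0.5, 0.75), c(0, 1, 2), 1, 0.95),
               class = "hubpool_grid_error")
})

test_that("coverage uses closed intervals", {
  lv <- c(0.25, 0.5, 0.75)
  vals <- c(0, 5, 10)
  expect_true(pi_coverage(lv, vals, 0, 0.5))    # boundary counts
  expect_true(pi_coverage(lv, vals, 10, 0.5))
  expect_false(pi_coverage(lv, vals, 10.0001, 0.5))
  expect_false(pi_coverage(lv, vals, -0.5, 0.5))
})

test_that("score_forecasts scores each model-task group once", {
  lv <- flusight_quantile_levels()
  hub <- two_normal_hub(task_grid = list(location = c("A", "B"),
                                         horizon = 0:1))
  fc <- generate_component_outputs(hub, "quantile")
  tg <- generate_target_series(hub)
  scores <- score_forecasts(fc, tg)
  expect_equal(nrow(scores), 2 * 4)   # 2 models x 4 tasks
  expect_true(all(scores$wis >= 0))
  expect_equal(scores$wis,
               scores$wis_overprediction + scores$wis_underprediction +
                 scores$wis_dispersion,
               tolerance = 1e-9)

  # degenerate forecast: all quantiles equal to the observation
  y <- 57
  perf <- validate_model_output(data.frame(
    model_id = "perfect", location = "A", output_type = "quantile",
    output_type_id = lv, value = y
  ), "location")
  s <- score_forecasts(perf, data.frame(location = "A", observation = y))
  expect_equal(s$wis, 0)
  expect_equal(s$abs_error, 0)
  expect_true(s$covered_50 && s$covered_95)

  # observation at the median: pure dispersion
  fc0 <- validate_model_output(data.frame(
    model_id = "n01", location = "A", output_type = "quantile",
    output_type_id = lv, value = qnorm(lv)
  ), "location")
  s0 <- score_forecasts(fc0, data.frame(location = "A", observation = 0))
  expect_equal(s0$wis, s0$wis_dispersion)
  expect_equal(s0$wis_overprediction + s0$wis_underprediction, 0)

  s3 <- score_forecasts(fc0, data.frame(location = "A", observation = 3))
  expect_equal(s3$wis, wis_oracle(lv, qnorm(lv), 3), tolerance = 1e-9)

  expect_error(
    score_forecasts(fc0, data.frame(location = "B", observation = 1)),
    class = "hubpool_join_error"
  )
})

test_that("relative metrics are ratios on the common task set", {
  lv <- flusight_quantile_levels()
  tasks <- list(location = c("A", "B", "C"), horizon = 0:3)
  hub <- hub_spec(
    models = list(
      list(model_id = "truth-model", family = "norm", mu = 110, sigma = 8),
      list(model_id = "wide-baseline", family = "norm", mu = 110, sigma = 16)
    ),
    task_grid = tasks,
    truth = list(family = "norm", mu = 110, sigma = 8), seed = 31
  )
  fc <- generate_component_outputs(hub, "quantile")
  tg <- generate_target_series(hub)
  scores <- score_forecasts(fc, tg)

  rel <- relative_metric(scores, "wide-baseline", "wis")
  expect_identical(rel$rwis[rel$model_id == "wide-baseline"], 1)
  # the true-distribution forecaster beats a doubled-spread baseline
  expect_lt(rel$rwis[rel$model_id == "truth-model"], 1)

  # scale property: halving every wis halves the ratio
  half <- scores
  half$wis[half$model_id == "truth-model"] <-
    scores$wis[scores$model_id == "wide-baseline"] / 2
  half$model_id[half$model_id == "truth-model"] <- "half-baseline"
  rel2 <- relative_metric(half, "wide-baseline", "wis")
  expect_equal(rel2$rwis[rel2$model_id == "half-baseline"], 0.5)

  expect_error(relative_metric(scores, "nope", "wis"),
               class = "hubpool_missing_baseline_error")

  summ <- summarize_scores(scores, "wide-baseline")
  expect_setequal(names(summ),
                  c("model_id", "wis", "mae", "cov50", "cov95",
                    "rwis", "rmae"))
  expect_identical(summ$rmae[summ$model_id == "wide-baseline"], 1)
})

test_that("aggregation is invariant to row order", {
  hub <- two_normal_hub(task_grid = list(location = c("A", "B"),
                                         horizon = 0:1))
  fc <- generate_component_outputs(hub, "quantile")
  tg <- generate_target_series(hub)
  s1 <- summarize_scores(score_forecasts(fc, tg))
  set.seed(9)
  shuf <- validate_model_output(
    as.data.frame(fc)[sample(nrow(fc)), ],
    task_id_names = attr(fc, "task_id_names")
  )
  s2 <- summarize_scores(score_forecasts(shuf, tg[sample(nrow(tg)), ]))
  expect_equal(s1, s2)
})
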