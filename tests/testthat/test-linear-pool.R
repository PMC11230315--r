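# Linear opinion pool: delegation for cdf/pmf/mean, the quantile
# reconstruction path, and stratified sample pooling.

test_that("cdf/pmf/mean paths are bitwise-equal to the mean simple ensemble", {
  hub <- two_normal_hub(cdf_value_grid = seq(60, 160, by = 10),
                        pmf_breaks = c(90, 110),
                        pmf_labels = c("low", "mid", "high"))
  tbl <- generate_component_outputs(hub, c("mean", "cdf", "pmf"))
  expect_identical(as.data.frame(linear_pool(tbl, model_id = "e")),
                   as.data.frame(simple_ensemble(tbl, model_id = "e")))

  t6 <- validate_model_output(table6_pmf(), c("target", "horizon"),
                              pmf_category_order = pmf_levels)
  expect_identical(linear_pool(t6)$value, simple_ensemble(t6)$value)
})

test_that("median inputs and weighted sample pooling are rejected", {
  hub <- two_normal_hub()
  med <- generate_component_outputs(hub, "median")
  expect_error(linear_pool(med), class = "hubpool_unsupported_type_error")
  samp <- generate_component_outputs(hub, "sample")
  w <- data.frame(model_id = c("A", "B"), weight = c(0.5, 0.5))
  expect_error(linear_pool(samp, weights = w),
               class = "hubpool_capability_error")
})

test_that("a single-model quantile pool reproduces the model", {
  # reproduction is limited by order-statistic interpolation between
  # adjacent midpoint samples: exact (1e-6) at interior levels, tail
  # curvature dominates at 0.01/0.99 and shrinks like 1/n^2
  lv <- flusight_quantile_levels()
  inner <- lv >= 0.025 & lv <= 0.975
  tbl <- normal_quantile_table(100, 10)
  lp <- linear_pool(tbl, n_samples = 1e4, model_id = "lp")
  expect_equal(unique(lp$model_id), "lp")
  expect_lt(max(abs(lp$value[inner] - tbl$value[inner])), 1e-4)
  expect_lt(max(abs(lp$value - tbl$value)), 5e-3)
  lp5 <- linear_pool(tbl, n_samples = 1e5)
  expect_lt(max(abs(lp5$value - tbl$value)), 5e-4)
  # identical components pool to the same distribution
  tbl2 <- normal_quantile_table(c(100, 100), c(10, 10))
  lp2 <- linear_pool(tbl2, n_samples = 1e4)
  expect_lt(max(abs(lp2$value - qnorm(lv, 100, 10))), 5e-3)
})

test_that("quantile LOP matches the brute-force mixture oracle", {
  lv <- flusight_quantile_levels()
  tbl <- normal_quantile_table(c(100, 120), c(10, 5))
  lp <- linear_pool(tbl, n_samples = 1e5, model_id = "lp")

  Fbar <- function(x) 0.5 * (pnorm(x, 100, 10) + pnorm(x, 120, 5))
  oracle <- vapply(lv, function(p) {
    uniroot(function(x) Fbar(x) - p, c(-100, 400), tol = 1e-10)$root
  }, 0)
  expect_lt(max(abs(lp$value - oracle)), 0.5)

  # mixture moments from the pooled quantile function
  th <- (seq_len(2e4) - 0.5) / 2e4
  d1 <- fit_quantile_distribution(lv, qnorm(lv, 100, 10))
  d2 <- fit_quantile_distribution(lv, qnorm(lv, 120, 5))
  pooled <- c(quasi_random_samples(d1, 1e5), quasi_random_samples(d2, 1e5))
  expect_equal(mean(pooled), 110, tolerance = 0.3)
  sigma2_lop <- 0.5 * (10^2 + 5^2) + 0.5 * ((100 - 110)^2 + (120 - 110)^2)
  expect_equal(var(pooled), sigma2_lop, tolerance = 0.02 * sigma2_lop)
})

test_that("weighted quantile LOP allocates draws by largest remainder", {
  lv <- flusight_quantile_levels()
  tbl <- normal_quantile_table(c(100, 120), c(10, 5))
  w <- data.frame(model_id = c("m1", "m2"), weight = c(0.75, 0.25))
  lp <- linear_pool(tbl, weights = w, n_samples = 2e4, model_id = "lp")
  Fbar <- function(x) 0.75 * pnorm(x, 100, 10) + 0.25 * pnorm(x, 120, 5)
  oracle <- vapply(lv, function(p) {
    uniroot(function(x) Fbar(x) - p, c(-100, 400), tol = 1e-10)$root
  }, 0)
  expect_lt(max(abs(lp$value - oracle)), 0.5)
})

test_that("mismatched level grids across models error", {
  lv <- flusight_quantile_levels()
  a <- data.frame(model_id = "a", h = 1, output_type = "quantile",
                  output_type_id = lv, value = qnorm(lv, 100, 10))
  b <- data.frame(model_id = "b", h = 1, output_type = "quantile",
                  output_type_id = c(0.25, 0.5, 0.75),
                  value = qnorm(c(0.25, 0.5, 0.75), 120, 5))
  tbl <- validate_model_output(rbind(a, b), "h")
  expect_error(linear_pool(tbl), class = "hubpool_grid_mismatch_error")
})

test_that("variance ordering: quantile average <= LOP on unequal means", {
  set.seed(5)
  lv <- flusight_quantile_levels()
  for (i in 1:5) {
    mus <- runif(3, 50, 150)
    sigmas <- runif(3, 2, 20)
    tbl <- normal_quantile_table(mus, sigmas)
    qa <- simple_ensemble(tbl)$value
    lp <- linear_pool(tbl, n_samples = 2e4)$value
    # variance proxy from the quantile function on the midpoint grid
    th <- (seq_len(2e4) - 0.5) / 2e4
    var_qa <- var(approx(lv, qa, xout = pmin(pmax(th, lv[1]), lv[23]))$y)
    var_lp <- var(approx(lv, lp, xout = pmin(pmax(th, lv[1]), lv[23]))$y)
    expect_lte(var_qa, var_lp * 1.001)
  }
})

test_that("tail family choice only moves the outer edges", {
  lv <- flusight_quantile_levels()
  tbl <- normal_quantile_table(c(100, 120), c(10, 5))
  lpn <- linear_pool(tbl, n_samples = 2e4, tail_dist = "norm")
  lpl <- linear_pool(tbl, n_samples = 2e4, tail_dist = "lnorm")
  inner <- lv >= 0.025 & lv <= 0.975
  expect_lt(max(abs(lpn$value[inner] - lpl$value[inner])), 1e-3 * 120)
})

test_that("sample pooling concatenates with collision-free re-indexing", {
  hub <- hub_spec(
    models = list(
      list(model_id = "A", family = "norm", mu = 100, sigma = 10),
      list(model_id = "B", family = "norm", mu = 120, sigma = 5),
      list(model_id = "C", family = "norm", mu = 110, sigma = 8)
    ),
    task_grid = list(location = "MA", horizon = 0),
    truth = list(family = "norm", mu = 110, sigma = 8),
    n_samples_per_model = 100, seed = 2
  )
  samp <- generate_component_outputs(hub, "sample")
  pooled <- linear_pool(samp, model_id = "lp")
  expect_equal(nrow(pooled), 300)
  expect_equal(length(unique(pooled$output_type_id)), 300)
  expect_setequal(sort(pooled$value), sort(samp$value))
})

test_that("subsetted sample pooling allocates 34/33/33 and keeps joints", {
  tbl <- joint_sample_table(n_models = 3, n_samples = 50, horizons = 0:3)
  tid <- attr(tbl, "task_id_names")
  compound <- c("reference_date", "location", "target")

  expect_true(validate_compound_taskids(tbl, compound, "target_end_date", tid))

  pooled <- pool_samples(tbl, task_ids = tid, model_id = "lp",
                         n_output_samples = 100,
                         compound_taskid_set = compound,
                         derived_tasks = "target_end_date", seed = 42)
  # every retained joint sample contributes one row per horizon
  expect_equal(nrow(pooled), 100 * 4)
  counts <- table(pooled$output_type_id)
  expect_true(all(counts == 4))
  expect_equal(length(counts), 100)
  # per-model allocation is 34/33/33 (largest remainder over 3 models);
  # recover the source model of each retained index by value matching
  src <- tbl$model_id[match(pooled$value, tbl$value)]
  per_index <- tapply(src, pooled$output_type_id, unique)
  expect_true(all(lengths(per_index) == 1))   # joint draws stay together
  expect_equal(sort(as.vector(table(unlist(per_index)))), c(33, 33, 34))

  expect_error(
    pool_samples(tbl, task_ids = tid, n_output_samples = 100),
    class = "hubpool_configuration_error"
  )
  expect_error(
    pool_samples(tbl, task_ids = tid, n_output_samples = 1000,
                 compound_taskid_set = compound,
                 derived_tasks = "target_end_date", seed = 1),
    class = "hubpool_insufficient_samples_error"
  )
})

test_that("compound task-ID validation detects broken joint structure", {
  tbl <- joint_sample_table(n_models = 2, n_samples = 20, horizons = 0:3)
  tid <- attr(tbl, "task_id_names")

  # marginal interpretation (all task IDs compound) is always consistent
  expect_true(validate_compound_taskids(tbl, tid, NULL, tid))

  # one sample index missing a horizon breaks the cross-product
  broken <- as.data.frame(tbl)
  broken <- broken[!(broken$model_id == "m1" & broken$output_type_id == "5" &
                       broken$horizon == 2), ]
  expect_false(validate_compound_taskids(
    broken, c("reference_date", "location", "target"), "target_end_date", tid
  ))

  # contradictory derived task value
  bad <- as.data.frame(tbl)
  bad$target_end_date[1] <- "1999-01-01"
  expect_false(validate_compound_taskids(
    bad, c("reference_date", "location", "target"), "target_end_date", tid
  ))
})
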