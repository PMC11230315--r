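# Fixtures built in code: printed example tables and small synthetic hubs.

# 12 quantile predictions (quartiles x 4 horizons) for one model.
table1_quantiles <- function() {
  data.frame(
    model_id = "team1-mod",
    loc = "MA",
    ref_date = "2022-12-17",
    h = rep(0:3, each = 3),
    target = "wk flu hosp",
    output_type = "quantile",
    output_type_id = rep(c(0.25, 0.5, 0.75), 4),
    value = c(514, 596, 713, 563, 664, 803, 469, 575, 705, 324, 408, 512),
    stringsAsFactors = FALSE
  )
}

# 12 PMF rows: 3 models x 4 ordered hospitalization-intensity categories.
table6_pmf <- function() {
  cats <- c("low", "moderate", "high", "very high")
  data.frame(
    model_id = rep(c("Flusight-baseline", "MOBS-GLEAM_FLUH", "PSI-DICE"),
                   each = 4),
    target = "wk flu hosp rate category",
    horizon = 1,
    output_type = "pmf",
    output_type_id = rep(cats, 3),
    value = c(0.000, 0.003, 0.073, 0.924,
              0.000, 0.002, 0.163, 0.835,
              0.013, 0.065, 0.218, 0.704),
    stringsAsFactors = FALSE
  )
}

pmf_levels <- c("low", "moderate", "high", "very high")

# Two-component normal hub used throughout: N(100, 10) and N(120, 5).
two_normal_hub <- function(task_grid = list(location = "MA", horizon = 0),
                           seed = 1, ...) {
  hub_spec(
    models = list(
      list(model_id = "A", family = "norm", mu = 100, sigma = 10),
      list(model_id = "B", family = "norm", mu = 120, sigma = 5)
    ),
    task_grid = task_grid,
    truth = list(family = "norm", mu = 110, sigma = 8),
    seed = seed,
    ...
  )
}

# Quantile rows for arbitrary normal components at a shared level grid.
normal_quantile_table <- function(mus, sigmas,
                                  levels = flusight_quantile_levels(),
                                  ids = paste0("m", seq_along(mus))) {
  rows <- do.call(rbind, lapply(seq_along(mus), function(i) {
    data.frame(model_id = ids[i], horizon = 1,
               output_type = "quantile",
               output_type_id = levels,
               value = qnorm(levels, mus[i], sigmas[i]),
               stringsAsFactors = FALSE)
  }))
  validate_model_output(rows, task_id_names = "horizon")
}

# Joint sample rows: each sample index spans all horizons for its model
# (one uniform per index, transformed per horizon).
joint_sample_table <- function(n_models = 3, n_samples = 100,
                               horizons = 0:3, seed = 7) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_models), function(i) {
    u <- runif(n_samples)
    do.call(rbind, lapply(horizons, function(h) {
      data.frame(model_id = paste0("m", i),
                 reference_date = "2022-12-17", location = "MA",
                 horizon = h,
                 target_end_date = format(as.Date("2022-12-17") + 7 * h),
                 target = "wk flu hosp",
                 output_type = "sample",
                 output_type_id = as.character(seq_len(n_samples)),
                 value = qnorm(u, 100 + 5 * h, 10),
                 stringsAsFactors = FALSE)
    }))
  }))
  validate_model_output(
    rows,
    task_id_names = c("reference_date", "location", "horizon",
                      "target_end_date", "target")
  )
}
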