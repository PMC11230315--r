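# Scoring of quantile-format forecasts: weighted interval score with its
# penalty decomposition, absolute error of the median, central-interval
# coverage, and relative skill versus a baseline model.

check_symmetric_grid <- function(levels) {
  if (anyNA(levels)) {
    hub_error("hubpool_grid_error", "quantile levels must be numeric")
  }
  levels <- sort(levels)
  if (!any(abs(levels - 0.5) < 1e-9)) {
    hub_error("hubpool_grid_error", "quantile grid must include level 0.5")
  }
  unpaired <- vapply(levels, function(l) {
    !any(abs(levels - (1 - l)) < 1e-9)
  }, TRUE)
  if (any(unpaired)) {
    hub_error("hubpool_grid_error", paste0(
      "unpaired quantile level(s): ",
      paste(format(levels[unpaired]), collapse = ", ")
    ))
  }
  levels
}

#' Weighted interval score of a quantile forecast
#'
#' The weighted interval score (WIS) of a forecast given as quantiles at a
#' symmetric level grid containing 0.5. With `K` central intervals of
#' nominal coverage \eqn{1 - \alpha_k} (lower/upper quantiles
#' \eqn{l_k, u_k}), median \eqn{m}, and observation \eqn{y}:
#' \deqn{WIS = \frac{1}{K + 1/2}\Big(\frac{|y - m|}{2} +
#'   \sum_k \frac{\alpha_k}{2} IS_{\alpha_k}(l_k, u_k, y)\Big)}
#' where \eqn{IS_\alpha = (u - l) + \frac{2}{\alpha}(l - y)1[y < l] +
#' \frac{2}{\alpha}(y - u)1[y > u]}. The score decomposes exactly into a
#' dispersion term (the interval widths), an over-prediction penalty
#' (observation below the forecast) and an under-prediction penalty; with
#' the grid `{0.5}` alone, WIS reduces to the absolute error of the
#' median.
#'
#' @param levels Quantile levels, symmetric about 0.5 and including 0.5.
#' @param values Forecast quantiles at `levels`.
#' @param y Observed value (scalar).
#' @return Named list with components `wis`, `overprediction`,
#'   `underprediction`, `dispersion` (`wis` is their exact sum).
#' @examples
#' wis(c(0.25, 0.5, 0.75), c(0, 5, 10), y = 12)
#' @export
wis <- function(levels, values, y) {
  stopifnot(length(levels) == length(values), length(y) == 1L)
  o <- order(levels)
  levels <- levels[o]
  values <- values[o]
  check_symmetric_grid(levels)
  m <- values[which.min(abs(levels - 0.5))]
  low_idx <- which(levels < 0.5 - 1e-9)
  K <- length(low_idx)
  denom <- K + 0.5

  disp <- 0
  over <- 0
  under <- 0
  for (i in low_idx) {
    alpha <- 2 * levels[i]
    l <- values[i]
    u <- values[which.min(abs(levels - (1 - levels[i])))]
    disp <- disp + (alpha / 2) * (u - l)
    if (y > u) over <- over + (y - u)     # (alpha/2) * (2/alpha) * (y - u)
    if (y < l) under <- under + (l - y)
  }
  if (y > m) over <- over + 0.5 * (y - m)
  if (y < m) under <- under + 0.5 * (m - y)
  disp <- disp / denom
  over <- over / denom
  under <- under / denom
  list(wis = disp + over + under,
       overprediction = over, underprediction = under, dispersion = disp)
}

#' Central prediction-interval coverage indicator
#'
#' Whether the observation falls inside the central interval of the given
#' nominal level (closed interval: boundary observations count as
#' covered). The grid must contain the pair of levels
#' `((1 - nominal)/2, (1 + nominal)/2)`.
#'
#' @inheritParams wis
#' @param nominal Nominal central coverage, e.g. 0.5 or 0.95.
#' @return Logical scalar.
#' @export
pi_coverage <- function(levels, values, y, nominal) {
  stopifnot(length(levels) == length(values), length(y) == 1L)
  lo <- (1 - nominal) / 2
  hi <- (1 + nominal) / 2
  i <- which(abs(levels - lo) < 1e-9)
  j <- which(abs(levels - hi) < 1e-9)
  if (length(i) != 1L || length(j) != 1L) {
    hub_error("hubpool_grid_error", paste0(
      "grid lacks the bounding pair for nominal coverage ", nominal
    ))
  }
  values[i] <= y && y <= values[j]
}

#' Score quantile forecasts against a target series
#'
#' Scores every (model, task group) of quantile predictions against its
#' observation: WIS with the over/under-prediction and dispersion
#' decomposition, absolute error of the median (the 0.5 quantile serves
#' as the point forecast), and 50%/95% central-interval coverage
#' indicators (NA when the grid lacks the needed levels).
#'
#' @param forecasts A `model_output` table of quantile predictions.
#' @param targets Target series data frame (task-key columns plus
#'   `observation`), see [validate_target_series()].
#' @param join_keys Column names (present in both the forecast task IDs
#'   and the target series) that link a forecast group to its observation.
#'   Defaults to the intersection.
#' @return A score table: one row per model and task group with columns
#'   `model_id`, the task-ID columns, `observation`, `wis`,
#'   `wis_overprediction`, `wis_underprediction`, `wis_dispersion`,
#'   `abs_error`, `covered_50`, `covered_95`.
#' @export
score_forecasts <- function(forecasts, targets, join_keys = NULL) {
  if (!inherits(forecasts, "model_output")) {
    forecasts <- validate_model_output(forecasts)
  }
  tid <- task_id_names(forecasts)
  forecasts <- forecasts[forecasts$output_type == "quantile", , drop = FALSE]
  if (nrow(forecasts) == 0L) {
    hub_error("hubpool_empty_input_error", "no quantile forecasts to score")
  }
  targets <- validate_target_series(targets)
  join_keys <- join_keys %||%
    intersect(tid, setdiff(names(targets), "observation"))
  if (length(join_keys) == 0L ||
      length(setdiff(join_keys, tid)) ||
      length(setdiff(join_keys, names(targets)))) {
    hub_error("hubpool_join_error",
              "join_keys must be task-ID columns present in the target series")
  }

  tkey <- group_key(targets, join_keys)
  fkey <- paste(forecasts$model_id, group_key(forecasts, tid), sep = "\r")
  groups <- split(seq_len(nrow(forecasts)), fkey)

  rows <- lapply(groups, function(idx) {
    sub <- forecasts[idx, , drop = FALSE]
    obs_at <- match(group_key(sub[1, , drop = FALSE], join_keys), tkey)
    if (is.na(obs_at)) {
      hub_error("hubpool_join_error", paste0(
        "no observation for forecast group: ",
        paste(join_keys, unlist(sub[1, join_keys]), sep = "=", collapse = " ")
      ))
    }
    y <- targets$observation[obs_at]
    lev <- otid_numeric(sub$output_type_id)
    s <- wis(lev, sub$value, y)
    m <- sub$value[which.min(abs(lev - 0.5))]
    cov50 <- tryCatch(pi_coverage(lev, sub$value, y, 0.5),
                      error = function(e) NA)
    cov95 <- tryCatch(pi_coverage(lev, sub$value, y, 0.95),
                      error = function(e) NA)
    cbind(sub[1, c("model_id", tid), drop = FALSE],
          data.frame(observation = y, wis = s$wis,
                     wis_overprediction = s$overprediction,
                     wis_underprediction = s$underprediction,
                     wis_dispersion = s$dispersion,
                     abs_error = abs(y - m),
                     covered_50 = cov50, covered_95 = cov95))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "task_id_names") <- tid
  out
}

#' Relative skill versus a baseline model
#'
#' Ratio of a model's mean score to the baseline's mean score, computed on
#' the intersection of scored tasks (inner join on the task-ID columns).
#' The baseline's own ratio is exactly 1; values below 1 indicate better
#' performance than the baseline.
#'
#' @param scores A score table from [score_forecasts()].
#' @param baseline_model_id Model ID of the baseline.
#' @param metric `"wis"` or `"mae"` (mean absolute error of the median).
#' @return Data frame with columns `model_id` and the ratio column
#'   (`rwis` or `rmae`).
#' @export
relative_metric <- function(scores, baseline_model_id,
                            metric = c("wis", "mae")) {
  metric <- match.arg(metric)
  col <- if (metric == "wis") "wis" else "abs_error"
  tid <- attr(scores, "task_id_names") %||%
    setdiff(names(scores),
            c("model_id", "observation", "wis", "wis_overprediction",
              "wis_underprediction", "wis_dispersion", "abs_error",
              "covered_50", "covered_95"))
  if (!baseline_model_id %in% scores$model_id) {
    hub_error("hubpool_missing_baseline_error", paste0(
      "baseline model '", baseline_model_id, "' has no scores"
    ))
  }
  base <- scores[scores$model_id == baseline_model_id, , drop = FALSE]
  bkey <- group_key(base, tid)
  models <- sort(unique(scores$model_id))
  ratio <- vapply(models, function(m) {
    sub <- scores[scores$model_id == m, , drop = FALSE]
    at <- match(group_key(sub, tid), bkey)
    keep <- !is.na(at)
    if (!any(keep)) {
      hub_error("hubpool_join_error", paste0(
        "model '", m, "' shares no scored tasks with the baseline"
      ))
    }
    mean(sub[[col]][keep]) / mean(base[[col]][at[keep]])
  }, 0)
  out <- data.frame(model_id = models, ratio = unname(ratio))
  names(out)[2] <- paste0("r", metric)
  out
}

#' Aggregate a score table by model
#'
#' Per-model summary of a score table: mean WIS, mean absolute error
#' (MAE), and empirical 50%/95% coverage rates; optionally relative WIS
#' and MAE versus a baseline model.
#'
#' @inheritParams relative_metric
#' @param baseline_model_id Optional baseline for `rwis`/`rmae` columns.
#' @return Data frame with one row per model: `model_id`, `wis`, `mae`,
#'   `cov50`, `cov95`, and (with a baseline) `rwis`, `rmae`.
#' @export
summarize_scores <- function(scores, baseline_model_id = NULL) {
  models <- sort(unique(scores$model_id))
  out <- do.call(rbind, lapply(models, function(m) {
    sub <- scores[scores$model_id == m, , drop = FALSE]
    data.frame(model_id = m,
               wis = mean(sub$wis),
               mae = mean(sub$abs_error),
               cov50 = mean(sub$covered_50, na.rm = TRUE),
               cov95 = mean(sub$covered_95, na.rm = TRUE))
  }))
  if (!is.null(baseline_model_id)) {
    out <- merge(out, relative_metric(scores, baseline_model_id, "wis"),
                 by = "model_id")
    out <- merge(out, relative_metric(scores, baseline_model_id, "mae"),
                 by = "model_id")
    out <- out[order(out$wis), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
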