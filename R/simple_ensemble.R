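# Row-group-wise aggregation of model outputs: quantile (Vincent)
# averaging for quantile inputs, linear pool for cdf/pmf, plain averages
# for point outputs.

#' Weighted median
#'
#' Smallest value whose cumulative normalized weight reaches 0.5; when the
#' cumulative weight hits 0.5 exactly at a value, that value is averaged
#' with the next larger one (so with equal weights and even `n` this
#' matches the usual sample-median convention).
#'
#' @param values Numeric vector.
#' @param weights Nonnegative weights, same length; must not all be zero.
#' @return The weighted median (length-1 numeric).
#' @examples
#' weighted_median(c(1, 2, 3), c(0.6, 0.2, 0.2)) # 1
#' weighted_median(1:4, rep(1, 4)) # 2.5
#' @export
weighted_median <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights))
  if (any(weights < 0) || anyNA(weights)) {
    hub_error("hubpool_weight_error", "weights must be nonnegative")
  }
  if (sum(weights) <= 0) {
    hub_error("hubpool_degenerate_weights_error", "all weights are zero")
  }
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  i <- which(cw >= 0.5 - 1e-12)[1]
  if (abs(cw[i] - 0.5) <= 1e-12 && i < length(v)) {
    (v[i] + v[i + 1]) / 2
  } else {
    v[i]
  }
}

# Resolve the aggregation into a function(x, w) -> scalar. Built-in mean
# and median fall back to their unweighted forms when weights are absent
# or uniform, so that equal explicit weights reproduce the unweighted
# ensemble bit for bit.
resolve_agg <- function(agg_fun, weighted) {
  if (is.character(agg_fun)) {
    agg_fun <- switch(agg_fun,
      mean = mean, median = stats::median,
      hub_error("hubpool_domain_error",
                paste0("unknown aggregation function: ", agg_fun))
    )
  }
  if (identical(agg_fun, mean)) {
    return(function(x, w) {
      if (is.null(w) || diff(range(w)) == 0) mean(x)
      else sum(w * x) / sum(w)
    })
  }
  if (identical(agg_fun, stats::median)) {
    return(function(x, w) {
      if (is.null(w) || diff(range(w)) == 0) stats::median(x)
      else weighted_median(x, w)
    })
  }
  if (!is.function(agg_fun)) {
    hub_error("hubpool_domain_error", "agg_fun must be a function")
  }
  takes_w <- "w" %in% names(formals(agg_fun))
  if (weighted && !takes_w) {
    hub_error("hubpool_capability_error",
              "agg_fun does not accept weights (no 'w' argument)")
  }
  if (takes_w) {
    function(x, w) agg_fun(x, w = w %||% rep(1 / length(x), length(x)))
  } else {
    function(x, w) agg_fun(x)
  }
}

#' Simple ensemble: aggregate predictions within each output group
#'
#' Combines model outputs by applying an aggregation function within each
#' unique combination of task-ID values, output type and output-type id.
#' With the default mean aggregation this yields a quantile (Vincent)
#' average for quantile inputs, a linear opinion pool for cdf and pmf
#' inputs, and an average of means/medians for point inputs. Sample
#' outputs cannot be combined this way and are rejected.
#'
#' By default every output group must contain the same set of models as
#' its siblings (groups sharing task-ID values and output type); this
#' prevents a model silently dropping out at a single quantile level.
#' Set `partial = "renormalize"` to average over whichever models are
#' present, renormalizing weights within the group.
#'
#' @param table A `model_output` table (validated if not already).
#' @param weights Optional weight table (`model_id`, `weight`, optional
#'   stratum columns); normalized via [validate_weights()]. `NULL` means
#'   equal weights.
#' @param agg_fun Aggregation: `"mean"` (default), `"median"`, or a
#'   function of a numeric vector `x` (and, to support weights, a
#'   numeric vector `w`).
#' @param model_id Name for the ensemble in the output (default
#'   `"hub-ensemble"`).
#' @param partial `"error"` (default) or `"renormalize"`; see Details.
#' @return A validated `model_output` table with one row per input group.
#' @examples
#' tbl <- data.frame(
#'   model_id = rep(c("a", "b"), each = 2), h = 1,
#'   output_type = "quantile", output_type_id = c(0.25, 0.75, 0.25, 0.75),
#'   value = c(514, 713, 600, 800)
#' )
#' simple_ensemble(validate_model_output(tbl, "h"))
#' @export
simple_ensemble <- function(table, weights = NULL, agg_fun = "mean",
                            model_id = "hub-ensemble",
                            partial = c("error", "renormalize")) {
  partial <- match.arg(partial)
  if (!inherits(table, "model_output")) table <- validate_model_output(table)
  tid <- task_id_names(table)
  if (nrow(table) == 0L) {
    hub_error("hubpool_empty_input_error", "no predictions to ensemble")
  }
  if (any(table$output_type == "sample")) {
    hub_error("hubpool_unsupported_type_error",
              "sample output type cannot be combined by simple_ensemble")
  }
  weighted <- !is.null(weights)
  f <- resolve_agg(agg_fun, weighted)

  w_row <- NULL
  if (weighted) {
    weights <- validate_weights(weights, table)
    strata <- attr(weights, "stratum_cols")
    wk <- paste(weights$model_id, group_key(weights, strata), sep = "\r")
    rk <- paste(table$model_id, group_key(table, strata), sep = "\r")
    w_row <- weights$weight[match(rk, wk)]
    if (anyNA(w_row)) {
      hub_error("hubpool_coverage_error",
                "weights do not cover every model/stratum in the table")
    }
  }

  taskkey <- group_key(table, tid)
  if (partial == "error") {
    # model sets must agree across output_type_ids within task/type
    sibling <- paste(taskkey, table$output_type, sep = "\r")
    for (idx in split(seq_len(nrow(table)), sibling)) {
      sets <- lapply(split(table$model_id[idx], table$output_type_id[idx]),
                     function(m) sort(unique(m)))
      if (length(unique(sets)) > 1L) {
        hub_error("hubpool_incomplete_group_error", paste0(
          "model sets differ across output_type_id groups for ",
          paste(tid, unlist(table[idx[1], tid]), sep = "=", collapse = " "),
          " output_type=", table$output_type[idx[1]],
          "; use partial = \"renormalize\" to average present models"
        ))
      }
    }
  }

  key <- paste(taskkey, table$output_type, table$output_type_id, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  first <- vapply(groups, `[`, 0L, 1L)
  agg <- vapply(groups, function(idx) {
    f(table$value[idx], if (weighted) w_row[idx] else NULL)
  }, 0)

  out <- table[first, c(tid, "output_type", "output_type_id"), drop = FALSE]
  out <- cbind(model_id = model_id, out, value = unname(agg))
  validate_model_output(out, task_id_names = tid,
                        pmf_category_order = attr(table, "pmf_category_order"))
}
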