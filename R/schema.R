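# Tabular model-output data model: validation, standardization, weights, IO.

hub_reserved_cols <- c("model_id", "output_type", "output_type_id", "value")

hub_output_types <- c("mean", "median", "quantile", "cdf", "pmf", "sample")

#' Quantile levels used by the FluSight forecasting challenge
#'
#' The 23 quantile levels at which FluSight forecasts are submitted:
#' 0.01, 0.025, 0.05, 0.10, ..., 0.90, 0.95, 0.975, 0.99.
#'
#' @return Numeric vector of length 23, strictly increasing, symmetric
#'   about 0.5.
#' @export
flusight_quantile_levels <- function() {
  c(0.01, 0.025, seq(0.05, 0.95, by = 0.05), 0.975, 0.99)
}

hub_error <- function(class, message) {
  stop(errorCondition(message, class = c(class, "hubpool_error", "error")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Canonical string form of an output_type_id: numbers rendered at 10
# significant digits so that grouping/equality is stable across readers,
# non-numeric ids kept verbatim.
canonical_otid <- function(x) {
  x <- as.character(x)
  num <- suppressWarnings(as.numeric(x))
  ok <- !is.na(num) & !is.na(x)
  x[ok] <- trimws(formatC(signif(num[ok], 10), format = "g", digits = 10))
  x
}

otid_numeric <- function(x) suppressWarnings(as.numeric(as.character(x)))

task_id_names <- function(table) attr(table, "task_id_names")

# Sort key: model_id, task ids in declared order, output_type, then
# output_type_id (numeric-aware; PMF categories by declared vocabulary).
canonical_order <- function(table, task_ids, pmf_category_order = NULL) {
  num <- otid_numeric(table$output_type_id)
  if (!is.null(pmf_category_order)) {
    r <- match(as.character(table$output_type_id), pmf_category_order)
    sel <- table$output_type == "pmf" & !is.na(r)
    num[sel] <- r[sel]
  }
  keys <- c(
    list(table$model_id),
    unname(as.list(table[task_ids])),
    list(table$output_type, is.na(num), num, as.character(table$output_type_id))
  )
  do.call(order, keys)
}

group_key <- function(table, cols) {
  if (length(cols) == 0L) return(rep("", nrow(table)))
  do.call(paste, c(unname(as.list(table[cols])), sep = "\r"))
}

#' Validate a raw table as standardized model output
#'
#' Checks a tabular set of predictions against the model-output data
#' standard: one prediction per row, identified by a model id, a set of
#' task-ID columns, an output type from the closed vocabulary
#' (mean, median, quantile, cdf, pmf, sample), an output-type id and a
#' numeric value. Per-type validity rules are enforced:
#'
#' * `mean`/`median`: `output_type_id` must be missing.
#' * `quantile`: `output_type_id` is a numeric quantile level in \[0, 1\].
#' * `cdf`: `value` in \[0, 1\] and nondecreasing within each
#'   model/task group in ascending `output_type_id` order.
#' * `pmf`: `value` in \[0, 1\] and summing to 1 (tolerance 1e-6) within
#'   each model/task group.
#' * `sample`: `output_type_id` is a non-missing sample index.
#'
#' Duplicate (model, task, type, id) rows are rejected. Rows are returned
#' in canonical order: model_id, task ids in declared order, output_type,
#' then output_type_id (numeric-aware).
#'
#' @param table A data frame of predictions.
#' @param task_id_names Character vector naming the task-ID columns of
#'   `table` (e.g. `c("location", "reference_date", "horizon")`). Defaults
#'   to the `task_id_names` attribute of `table`, or to all non-reserved
#'   columns.
#' @param pmf_category_order Optional character vector giving the ordinal
#'   order of PMF categories (e.g. `c("low", "moderate", "high",
#'   "very high")`); used for canonical sorting. Unordered categories sort
#'   lexicographically.
#' @return The validated table, classed `"model_output"`, with attributes
#'   `task_id_names` and `pmf_category_order`, sorted canonically.
#' @examples
#' tbl <- data.frame(
#'   model_id = "team1-mod", loc = "MA", h = 0,
#'   output_type = "quantile", output_type_id = c(0.25, 0.5, 0.75),
#'   value = c(514, 596, 713)
#' )
#' validate_model_output(tbl, task_id_names = c("loc", "h"))
#' @export
validate_model_output <- function(table, task_id_names = NULL,
                                  pmf_category_order = NULL) {
  tid <- task_id_names %||% attr(table, "task_id_names")
  pmf_category_order <- pmf_category_order %||% attr(table, "pmf_category_order")
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(tid)) tid <- setdiff(names(table), hub_reserved_cols)

  clash <- intersect(tid, hub_reserved_cols)
  if (length(clash)) {
    hub_error("hubpool_schema_error", paste0(
      "task_id_names clash with reserved column(s): ",
      paste(clash, collapse = ", ")
    ))
  }
  required <- c("model_id", tid, "output_type", "output_type_id", "value")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    hub_error("hubpool_schema_error", paste0(
      "missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  table <- table[required]
  table$model_id <- as.character(table$model_id)
  table$output_type <- as.character(table$output_type)

  bad_type <- setdiff(unique(table$output_type), hub_output_types)
  if (length(bad_type)) {
    hub_error("hubpool_schema_error", paste0(
      "unknown output_type value(s): ", paste(bad_type, collapse = ", ")
    ))
  }
  value <- suppressWarnings(as.numeric(table$value))
  if (anyNA(value) || any(!is.finite(value))) {
    hub_error("hubpool_schema_error", "value column must be finite numeric")
  }
  table$value <- value

  otid <- as.character(table$output_type_id)
  otid[!is.na(otid) & otid == ""] <- NA_character_
  ot <- table$output_type

  pt <- ot %in% c("mean", "median")
  if (any(pt & !is.na(otid))) {
    hub_error("hubpool_schema_error",
              "output_type_id must be missing for mean/median predictions")
  }
  qt <- ot == "quantile"
  if (any(qt)) {
    lev <- otid_numeric(otid[qt])
    if (anyNA(lev)) {
      hub_error("hubpool_schema_error",
                "quantile output_type_id must be numeric")
    }
    if (any(lev < 0 | lev > 1)) {
      hub_error("hubpool_domain_error",
                "quantile level (output_type_id) outside [0, 1]")
    }
  }
  if (any(ot == "sample" & is.na(otid))) {
    hub_error("hubpool_schema_error",
              "sample output_type_id (sample index) must not be missing")
  }
  probs <- ot %in% c("cdf", "pmf")
  if (any(probs & (table$value < 0 | table$value > 1))) {
    hub_error("hubpool_domain_error",
              "cdf/pmf value outside [0, 1]")
  }
  otid <- canonical_otid(otid)
  table$output_type_id <- otid

  key <- paste(table$model_id, group_key(table, tid), ot, otid, sep = "\r")
  if (anyDuplicated(key)) {
    hub_error("hubpool_duplicate_error", paste0(
      "duplicate prediction rows for (model_id, task ids, output_type, ",
      "output_type_id)"
    ))
  }

  grp <- paste(table$model_id, group_key(table, tid), sep = "\r")
  cdf_rows <- which(ot == "cdf")
  if (length(cdf_rows)) {
    for (idx in split(cdf_rows, grp[cdf_rows])) {
      num <- otid_numeric(otid[idx])
      o <- if (anyNA(num)) order(otid[idx]) else order(num)
      v <- round(table$value[idx][o], 12)
      if (is.unsorted(v)) {
        hub_error("hubpool_monotonicity_error", paste0(
          "non-monotone cdf values in group: model_id=",
          table$model_id[idx[1]], " ",
          paste(tid, unlist(table[idx[1], tid]), sep = "=", collapse = " ")
        ))
      }
    }
  }
  pmf_rows <- which(ot == "pmf")
  if (length(pmf_rows)) {
    sums <- vapply(split(table$value[pmf_rows], grp[pmf_rows]), sum, 0)
    if (any(abs(sums - 1) > 1e-6)) {
      i <- pmf_rows[match(names(sums)[abs(sums - 1) > 1e-6][1], grp[pmf_rows])]
      hub_error("hubpool_normalization_error", paste0(
        "pmf probabilities do not sum to 1 (tolerance 1e-6) in group: ",
        "model_id=", table$model_id[i], " ",
        paste(tid, unlist(table[i, tid]), sep = "=", collapse = " ")
      ))
    }
  }

  table <- table[canonical_order(table, tid, pmf_category_order), , drop = FALSE]
  rownames(table) <- NULL
  attr(table, "task_id_names") <- tid
  attr(table, "pmf_category_order") <- pmf_category_order
  class(table) <- c("model_output", "data.frame")
  table
}

#' Standardize arbitrarily named prediction columns to model output
#'
#' Renames columns of a raw prediction table (for example, a table pulled
#' from an external forecast repository with columns like `model`, `class`,
#' `quantile`) to the standard model-output column names, then validates
#' the result with [validate_model_output()].
#'
#' @param table A data frame of predictions.
#' @param column_mapping Named character vector mapping source column names
#'   to standard names, e.g.
#'   `c(model = "model_id", class = "output_type", quantile = "output_type_id")`.
#'   Unmapped standard columns must already be present under their standard
#'   name. Columns that are neither mapped, standard, nor task IDs are
#'   dropped.
#' @inheritParams validate_model_output
#' @return A validated `model_output` table.
#' @export
standardize_table <- function(table, column_mapping = NULL,
                              task_id_names = NULL,
                              pmf_category_order = NULL) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (length(column_mapping)) {
    if (is.null(names(column_mapping)) || any(names(column_mapping) == "")) {
      hub_error("hubpool_schema_error",
                "column_mapping must be a named vector (source = standard)")
    }
    absent <- setdiff(names(column_mapping), names(table))
    if (length(absent)) {
      hub_error("hubpool_schema_error", paste0(
        "column_mapping references absent column(s): ",
        paste(absent, collapse = ", ")
      ))
    }
    names(table)[match(names(column_mapping), names(table))] <-
      unname(column_mapping)
  }
  validate_model_output(table, task_id_names = task_id_names,
                        pmf_category_order = pmf_category_order)
}

#' Validate and normalize a table of model weights
#'
#' Checks a weight table against the models present in a model-output
#' table, restricts it to those models, and normalizes weights to sum to
#' one within each stratum (a stratum is a combination of values of any
#' optional weight columns that are also task IDs of `table`; with no
#' stratum columns there is a single stratum).
#'
#' @param weights Data frame with columns `model_id`, `weight`, and
#'   optionally a subset of the task-ID columns of `table`.
#' @param table A validated `model_output` table (see
#'   [validate_model_output()]).
#' @return The normalized weight table (weights sum to 1 per stratum),
#'   with a `stratum_cols` attribute.
#' @export
validate_weights <- function(weights, table) {
  tid <- task_id_names(table)
  weights <- as.data.frame(weights, stringsAsFactors = FALSE)
  missing <- setdiff(c("model_id", "weight"), names(weights))
  if (length(missing)) {
    hub_error("hubpool_schema_error", paste0(
      "weights table missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  strata_cols <- intersect(setdiff(names(weights), c("model_id", "weight")), tid)
  weights <- weights[c("model_id", strata_cols, "weight")]
  weights$model_id <- as.character(weights$model_id)
  weights$weight <- as.numeric(weights$weight)
  if (anyNA(weights$weight) || any(weights$weight < 0)) {
    hub_error("hubpool_weight_error", "weights must be nonnegative and non-missing")
  }

  models <- unique(table$model_id)
  uncovered <- setdiff(models, weights$model_id)
  if (length(uncovered)) {
    hub_error("hubpool_coverage_error", paste0(
      "model(s) in table absent from weights: ",
      paste(uncovered, collapse = ", ")
    ))
  }
  weights <- weights[weights$model_id %in% models, , drop = FALSE]

  strat <- group_key(weights, strata_cols)
  for (idx in split(seq_len(nrow(weights)), strat)) {
    ids <- weights$model_id[idx]
    if (anyDuplicated(ids)) {
      hub_error("hubpool_weight_error",
                "a model_id appears more than once within a stratum")
    }
    if (length(setdiff(models, ids))) {
      hub_error("hubpool_coverage_error",
                "every model must appear exactly once per stratum")
    }
    s <- sum(weights$weight[idx])
    if (s <= 0) {
      hub_error("hubpool_degenerate_weights_error",
                "all weights are zero within a stratum")
    }
    weights$weight[idx] <- weights$weight[idx] / s
  }
  rownames(weights) <- NULL
  attr(weights, "stratum_cols") <- strata_cols
  weights
}

#' Read / write standardized tables as CSV
#'
#' Plain-text (UTF-8, header row) readers and writers for model-output
#' tables, weight tables, and target time series. Numeric values are
#' written at full double precision (15 significant digits) so a
#' write-read round trip is value-stable.
#'
#' @param file Path to a CSV file.
#' @inheritParams validate_model_output
#' @return `read_model_output()` returns a validated `model_output` table;
#'   `read_target_series()` and `read_weights()` return data frames.
#' @name hub_io
NULL

#' @rdname hub_io
#' @export
read_model_output <- function(file, task_id_names = NULL,
                              pmf_category_order = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(output_type_id = "character"))
  validate_model_output(raw, task_id_names = task_id_names,
                        pmf_category_order = pmf_category_order)
}

#' @rdname hub_io
#' @param table Table to write.
#' @export
write_model_output <- function(table, file) {
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                                 trim = TRUE),
           formatC(x, format = "g", digits = 15))
  })
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE, na = "")
  invisible(file)
}

#' @rdname hub_io
#' @export
read_target_series <- function(file) {
  targets <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_target_series(targets)
}

#' @rdname hub_io
#' @export
read_weights <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Validate a target time-series table
#'
#' A target series holds one observed value per task key (e.g. date and
#' location); observations must be finite and task keys unique.
#'
#' @param targets Data frame with an `observation` column plus task-key
#'   columns.
#' @return The validated data frame.
#' @export
validate_target_series <- function(targets) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  if (!"observation" %in% names(targets)) {
    hub_error("hubpool_schema_error",
              "target series missing required column: observation")
  }
  obs <- suppressWarnings(as.numeric(targets$observation))
  if (anyNA(obs) || any(!is.finite(obs))) {
    hub_error("hubpool_schema_error", "observations must be finite numeric")
  }
  targets$observation <- obs
  keys <- setdiff(names(targets), "observation")
  if (anyDuplicated(group_key(targets, keys))) {
    hub_error("hubpool_duplicate_error",
              "duplicate task keys in target series")
  }
  targets
}
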