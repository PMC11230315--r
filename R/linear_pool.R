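# Linear opinion pool F_LOP(x) = sum_i w_i F_i(x) across output types.
# cdf/pmf/mean reduce to group-wise weighted means; quantile inputs go
# through distribution reconstruction + quasi-random sampling; sample
# inputs are pooled (optionally subset) with joint structure preserved.

# Integer allocation of a total among weights by largest remainder;
# ties broken by position (models are passed in model_id order).
largest_remainder <- function(w, total) {
  q <- w / sum(w) * total
  base <- floor(q)
  r <- as.integer(round(total - sum(base)))
  counts <- as.integer(base)
  if (r > 0) {
    extra <- order(-(q - base), seq_along(q))[seq_len(r)]
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

#' Linear opinion pool ensemble
#'
#' Computes the linear opinion pool (LOP, a mixture of the component
#' predictive distributions) for model outputs of type mean, quantile,
#' cdf, pmf, or sample. For cdf, pmf and mean output types the LOP equals
#' a group-wise weighted mean of values and is delegated to
#' [simple_ensemble()]. For quantile inputs, each component distribution
#' is reconstructed from its quantiles ([fit_quantile_distribution()]),
#' deterministic quasi-random samples are drawn from each and pooled, and
#' the ensemble quantiles are read from the pooled sample at the input
#' levels. Sample inputs are pooled by concatenation (equally weighted
#' only), optionally subset to `n_output_samples` by a stratified draw
#' that keeps joint samples intact; see [pool_samples()].
#'
#' The median output type has no meaningful LOP and is rejected.
#'
#' @inheritParams simple_ensemble
#' @param n_samples Number of quasi-random samples per component model for
#'   the quantile path (default 1e4). With weights, a model receives a
#'   weight-proportional share of `n_samples * n_models` draws (largest
#'   remainder allocation).
#' @param tail_dist Tail family for distribution reconstruction on the
#'   quantile path: `"norm"` (default), `"lnorm"`, or `"cauchy"`.
#' @param n_output_samples Optional total number of samples to return on
#'   the sample path; requires `compound_taskid_set`.
#' @param compound_taskid_set Task-ID names that jointly identify one
#'   modeled unit for sample predictions (task IDs outside the set vary
#'   within a single joint sample).
#' @param derived_tasks Task-ID names whose values are a deterministic
#'   function of the other task IDs (e.g. target date = reference date +
#'   horizon).
#' @param seed Integer seed for the random subset of sample indices when
#'   `n_output_samples` is given.
#' @return A validated `model_output` table.
#' @export
linear_pool <- function(table, weights = NULL, model_id = "hub-ensemble",
                        n_samples = 1e4, tail_dist = "norm",
                        n_output_samples = NULL,
                        compound_taskid_set = NULL,
                        derived_tasks = NULL, seed = NULL) {
  if (!inherits(table, "model_output")) table <- validate_model_output(table)
  tid <- task_id_names(table)
  if (nrow(table) == 0L) {
    hub_error("hubpool_empty_input_error", "no predictions to ensemble")
  }
  if (any(table$output_type == "median")) {
    hub_error("hubpool_unsupported_type_error",
              "median output type is not supported by linear_pool")
  }
  if (!is.null(weights) && any(table$output_type == "sample")) {
    hub_error("hubpool_capability_error",
              "only equally-weighted linear pools of samples are supported")
  }

  pieces <- list()
  direct <- table$output_type %in% c("mean", "cdf", "pmf")
  if (any(direct)) {
    sub <- table[direct, , drop = FALSE]
    attr(sub, "task_id_names") <- tid
    attr(sub, "pmf_category_order") <- attr(table, "pmf_category_order")
    class(sub) <- class(table)
    pieces$direct <- simple_ensemble(sub, weights = weights,
                                     agg_fun = "mean", model_id = model_id)
  }
  if (any(table$output_type == "quantile")) {
    sub <- table[table$output_type == "quantile", , drop = FALSE]
    pieces$quantile <- linear_pool_quantile(
      sub, weights = weights, task_ids = tid, model_id = model_id,
      n_samples = n_samples, tail_dist = tail_dist
    )
  }
  if (any(table$output_type == "sample")) {
    sub <- table[table$output_type == "sample", , drop = FALSE]
    pieces$sample <- pool_samples(
      sub, task_ids = tid, model_id = model_id,
      n_output_samples = n_output_samples,
      compound_taskid_set = compound_taskid_set,
      derived_tasks = derived_tasks, seed = seed
    )
  }
  out <- do.call(rbind, lapply(unname(pieces), as.data.frame))
  validate_model_output(out, task_id_names = tid,
                        pmf_category_order = attr(table, "pmf_category_order"))
}

#' Linear pool of quantile predictions
#'
#' The three-step quantile LOP: (1) reconstruct each component model's
#' distribution from its (level, value) pairs with a monotone spline
#' interior and `tail_dist` tails; (2) draw deterministic quasi-random
#' samples from each reconstructed distribution (a weight-proportional
#' share of `n_samples * n_models` draws per model); (3) pool all samples
#' and extract the empirical quantiles (type-5 order-statistic
#' interpolation, the inverse of the midpoint empirical CDF) at exactly
#' the input level grid. All component models within a task group must
#' report the same level grid.
#'
#' @param table Quantile-type rows of a `model_output` table.
#' @param task_ids Character vector of task-ID column names.
#' @inheritParams linear_pool
#' @return Data frame of ensemble quantile rows (one per task group and
#'   level).
#' @export
linear_pool_quantile <- function(table, weights = NULL, task_ids = NULL,
                                 model_id = "hub-ensemble",
                                 n_samples = 1e4, tail_dist = "norm") {
  tid <- task_ids %||% task_id_names(table)
  stopifnot(all(table$output_type == "quantile"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    hub_error("hubpool_domain_error", "n_samples must be a positive integer")
  }
  wtab <- NULL
  if (!is.null(weights)) {
    wtab <- validate_weights(weights, structure(
      as.data.frame(table), task_id_names = tid,
      class = c("model_output", "data.frame")
    ))
    if (length(attr(wtab, "stratum_cols"))) {
      hub_error("hubpool_capability_error",
                "per-stratum weights are not supported on the quantile path")
    }
  }

  taskkey <- group_key(table, tid)
  out <- lapply(split(seq_len(nrow(table)), taskkey), function(idx) {
    sub <- table[idx, , drop = FALSE]
    models <- sort(unique(sub$model_id))
    per_model <- lapply(models, function(m) {
      rows <- sub[sub$model_id == m, , drop = FALSE]
      lev <- otid_numeric(rows$output_type_id)
      o <- order(lev)
      list(levels = lev[o], values = rows$value[o])
    })
    grid <- per_model[[1]]$levels
    same <- vapply(per_model, function(p) {
      length(p$levels) == length(grid) && all(abs(p$levels - grid) < 1e-9)
    }, TRUE)
    if (!all(same)) {
      hub_error("hubpool_grid_mismatch_error", paste0(
        "quantile level grids differ across models in group ",
        paste(tid, unlist(sub[1, tid]), sep = "=", collapse = " ")
      ))
    }
    w <- if (is.null(wtab)) rep(1 / length(models), length(models))
         else wtab$weight[match(models, wtab$model_id)]
    counts <- largest_remainder(w, n_samples * length(models))
    pooled <- unlist(lapply(seq_along(models), function(i) {
      if (counts[i] == 0L) return(numeric(0))
      d <- tryCatch(
        fit_quantile_distribution(per_model[[i]]$levels,
                                  per_model[[i]]$values, tail_dist),
        error = function(e) {
          hub_error(class(e)[1], paste0(
            "model ", models[i], ", group ",
            paste(tid, unlist(sub[1, tid]), sep = "=", collapse = " "),
            ": ", conditionMessage(e)
          ))
        }
      )
      quasi_random_samples(d, counts[i])
    }))
    # type 5 inverts the midpoint empirical CDF exactly at sample
    # midpoints, so identical components reproduce their inputs up to
    # local interpolation error
    qs <- stats::quantile(pooled, probs = grid, type = 5, names = FALSE)
    meta <- sub[rep(1L, length(grid)), tid, drop = FALSE]
    cbind(model_id = model_id, meta,
          output_type = "quantile",
          output_type_id = canonical_otid(grid),
          value = qs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool sample predictions across models
#'
#' Concatenates equally-weighted sample predictions from all models into a
#' single ensemble sample set, re-indexing `output_type_id` with dense
#' integers (assigned in model then original-index order within each
#' compound unit) so indices never collide. If `n_output_samples` is
#' given, a stratified random subset is taken instead: each model
#' contributes `floor(n/N)` samples plus a largest-remainder share, with
#' sample indices (entire joint draws over the compound unit) selected
#' uniformly without replacement, so all rows sharing a selected index are
#' kept together.
#'
#' @param table Sample-type rows of a `model_output` table.
#' @inheritParams linear_pool
#' @inheritParams linear_pool_quantile
#' @return Data frame of pooled sample rows.
#' @export
pool_samples <- function(table, task_ids = NULL, model_id = "hub-ensemble",
                         n_output_samples = NULL,
                         compound_taskid_set = NULL, derived_tasks = NULL,
                         seed = NULL) {
  tid <- task_ids %||% task_id_names(table)
  stopifnot(all(table$output_type == "sample"))
  subsetting <- !is.null(n_output_samples)
  if (subsetting && is.null(compound_taskid_set)) {
    hub_error("hubpool_configuration_error",
              "n_output_samples requires a compound_taskid_set")
  }
  compound <- compound_taskid_set %||% tid
  if (length(setdiff(compound, tid))) {
    hub_error("hubpool_configuration_error",
              "compound_taskid_set must be a subset of the task IDs")
  }
  if (length(setdiff(derived_tasks, tid))) {
    hub_error("hubpool_configuration_error",
              "derived_tasks must be a subset of the task IDs")
  }
  if (subsetting &&
      !validate_compound_taskids(table, compound, derived_tasks, tid)) {
    hub_error("hubpool_validation_error", paste0(
      "compound_taskid_set is inconsistent with the joint structure of ",
      "the provided sample predictions"
    ))
  }

  unitkey <- group_key(table, setdiff(compound, derived_tasks))
  models_all <- sort(unique(table$model_id))

  selected <- rep(TRUE, nrow(table))
  if (subsetting) {
    n_out <- as.integer(n_output_samples)
    counts <- largest_remainder(rep(1, length(models_all)), n_out)
    if (!is.null(seed)) set.seed(as.integer(seed))
    units <- sort(unique(unitkey))
    for (u in units) {
      for (i in seq_along(models_all)) {
        rows <- which(unitkey == u & table$model_id == models_all[i])
        ids <- sort(unique(table$output_type_id[rows]))
        if (length(ids) < counts[i]) {
          hub_error("hubpool_insufficient_samples_error", paste0(
            "model ", models_all[i], " has ", length(ids),
            " sample indices but ", counts[i], " are required"
          ))
        }
        keep <- if (length(ids) == counts[i]) ids
                else sample(ids, counts[i])
        drop <- rows[!(table$output_type_id[rows] %in% keep)]
        selected[drop] <- FALSE
      }
    }
  }

  out <- as.data.frame(table)[selected, , drop = FALSE]
  ukey <- unitkey[selected]
  # dense integer re-indexing per compound unit, (model_id, original index)
  pairkey <- paste(out$model_id, out$output_type_id, sep = "\r")
  id_num <- otid_numeric(out$output_type_id)
  new_id <- integer(nrow(out))
  for (idx in split(seq_len(nrow(out)), ukey)) {
    o <- idx[order(out$model_id[idx], is.na(id_num[idx]), id_num[idx],
                   out$output_type_id[idx])]
    new_id[o] <- match(pairkey[o], unique(pairkey[o]))
  }
  out$output_type_id <- as.character(new_id)
  out$model_id <- model_id
  rownames(out) <- NULL
  out
}

#' Check a compound task-ID set against sample predictions
#'
#' Predicate: `TRUE` iff, within each model and compound unit (a
#' combination of values of the non-derived compound task IDs), every
#' sample index spans the same complete set of combinations of the
#' remaining (non-compound, non-derived) task IDs, and every derived task
#' ID is a deterministic function of the other task IDs.
#'
#' @param table Sample-type rows of a `model_output` table.
#' @param compound_taskid_set Task-ID names identifying one modeled unit.
#' @param derived_tasks Task-ID names derived from other task IDs.
#' @param task_ids Character vector of all task-ID column names.
#' @return Logical scalar.
#' @export
validate_compound_taskids <- function(table, compound_taskid_set,
                                      derived_tasks = NULL,
                                      task_ids = NULL) {
  tid <- task_ids %||% task_id_names(table)
  stopifnot(all(table$output_type == "sample"))
  compound <- setdiff(compound_taskid_set, derived_tasks)
  free <- setdiff(tid, c(compound_taskid_set, derived_tasks))

  # derived columns must be functions of the non-derived task IDs
  for (d in derived_tasks) {
    src <- group_key(table, setdiff(tid, derived_tasks))
    n_vals <- vapply(split(as.character(table[[d]]), src),
                     function(v) length(unique(v)), 0L)
    if (any(n_vals > 1L)) return(FALSE)
  }

  mk <- paste(table$model_id, group_key(table, compound), sep = "\r")
  for (idx in split(seq_len(nrow(table)), mk)) {
    combos <- group_key(table[idx, , drop = FALSE], free)
    full <- sort(unique(combos))
    per_id <- split(combos, table$output_type_id[idx])
    ok <- vapply(per_id, function(cc) {
      length(cc) == length(full) && identical(sort(cc), full)
    }, TRUE)
    if (!all(ok)) return(FALSE)
  }
  TRUE
}
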