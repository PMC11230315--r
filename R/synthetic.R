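# Synthetic miniature forecast hub: component models with known
# parametric predictive distributions emitted in all six output types,
# plus observations drawn from a designated truth distribution. Gives
# every ensembling and scoring path a closed-form ground truth.

hub_families <- c("norm", "lnorm", "point")

# A component distribution: vectorized q/p/mean/median over tasks.
# Parameters may be scalars (recycled) or length-n_tasks vectors.
make_dist <- function(family, pars, n_tasks) {
  rec <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) rep(x, n_tasks)
    else if (length(x) == n_tasks) x
    else hub_error("hubpool_spec_error",
                   "distribution parameters must be scalar or per-task")
  }
  switch(family,
    norm = {
      mu <- rec(pars$mu); sigma <- rec(pars$sigma)
      if (any(sigma <= 0)) hub_error("hubpool_spec_error", "sigma must be > 0")
      list(q = function(p, t) stats::qnorm(p, mu[t], sigma[t]),
           p = function(x, t) stats::pnorm(x, mu[t], sigma[t]),
           mean = function(t) mu[t], median = function(t) mu[t])
    },
    lnorm = {
      ml <- rec(pars$meanlog); sl <- rec(pars$sdlog)
      if (any(sl <= 0)) hub_error("hubpool_spec_error", "sdlog must be > 0")
      list(q = function(p, t) stats::qlnorm(p, ml[t], sl[t]),
           p = function(x, t) stats::plnorm(x, ml[t], sl[t]),
           mean = function(t) exp(ml[t] + sl[t]^2 / 2),
           median = function(t) exp(ml[t]))
    },
    point = {
      v <- rec(pars$value)
      list(q = function(p, t) v[t],
           p = function(x, t) as.numeric(x >= v[t]),
           mean = function(t) v[t], median = function(t) v[t])
    },
    hub_error("hubpool_spec_error", paste0("unknown family: ", family))
  )
}

#' Specify a synthetic forecast hub
#'
#' Describes a miniature forecast hub: a task grid, a set of component
#' models each with a known parametric predictive distribution per task,
#' a designated truth distribution, the quantile level grid, and the
#' discretizations used for cdf and pmf output.
#'
#' @param models List of model specifications, each a list with
#'   `model_id`, `family` (`"norm"`, `"lnorm"`, or `"point"`), and the
#'   family's parameters (`mu`/`sigma`, `meanlog`/`sdlog`, or `value`),
#'   given as scalars or per-task vectors.
#' @param task_grid Either a data frame of task combinations or a named
#'   list of value vectors crossed with `expand.grid()`.
#' @param truth Distribution specification (like a model, without
#'   `model_id`) from which observations are drawn.
#' @param quantile_levels Quantile levels emitted for the quantile output
#'   type; default the 23 FluSight levels.
#' @param cdf_value_grid Target-variable values at which cdf rows are
#'   emitted (required to generate cdf output).
#' @param pmf_breaks Strictly increasing finite cut points defining
#'   `length(pmf_breaks) + 1` ordered bins for pmf output.
#' @param pmf_labels Labels of the pmf bins (default `"bin1"`, ...).
#' @param n_samples_per_model Number of sample rows per model and task
#'   (or per joint unit when samples are joint); default 100.
#' @param seed Integer seed controlling sample and observation draws.
#' @return A `hub_spec` object.
#' @examples
#' spec <- hub_spec(
#'   models = list(
#'     list(model_id = "A", family = "norm", mu = 100, sigma = 10),
#'     list(model_id = "B", family = "norm", mu = 120, sigma = 5)
#'   ),
#'   task_grid = list(location = "MA", horizon = 0:1),
#'   truth = list(family = "norm", mu = 110, sigma = 8)
#' )
#' @export
hub_spec <- function(models, task_grid, truth,
                     quantile_levels = flusight_quantile_levels(),
                     cdf_value_grid = NULL,
                     pmf_breaks = NULL, pmf_labels = NULL,
                     n_samples_per_model = 100, seed = 1) {
  if (is.data.frame(task_grid)) {
    tasks <- as.data.frame(task_grid, stringsAsFactors = FALSE)
  } else {
    tasks <- expand.grid(task_grid, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  }
  if (nrow(tasks) == 0L) hub_error("hubpool_spec_error", "empty task grid")
  quantile_levels <- sort(as.numeric(quantile_levels))
  if (any(quantile_levels <= 0 | quantile_levels >= 1)) {
    hub_error("hubpool_spec_error", "quantile levels must lie in (0, 1)")
  }
  if (any(abs(sort(1 - quantile_levels) - quantile_levels) > 1e-9)) {
    hub_error("hubpool_spec_error",
              "quantile level grid must be symmetric about 0.5")
  }
  if (!is.null(pmf_breaks)) {
    pmf_breaks <- as.numeric(pmf_breaks)
    if (anyNA(pmf_breaks) || any(!is.finite(pmf_breaks)) ||
        is.unsorted(pmf_breaks, strictly = TRUE)) {
      hub_error("hubpool_spec_error",
                "pmf_breaks must be finite and strictly increasing")
    }
    if (is.null(pmf_labels)) {
      pmf_labels <- paste0("bin", seq_len(length(pmf_breaks) + 1))
    }
    if (length(pmf_labels) != length(pmf_breaks) + 1) {
      hub_error("hubpool_spec_error",
                "need length(pmf_breaks) + 1 pmf labels")
    }
  }
  ids <- vapply(models, function(m) m$model_id %||% "", "")
  if (any(ids == "") || anyDuplicated(ids)) {
    hub_error("hubpool_spec_error", "models need unique model_id entries")
  }
  for (m in models) make_dist(m$family, m, nrow(tasks))   # validate params
  make_dist(truth$family, truth, nrow(tasks))

  structure(
    list(models = models, tasks = tasks, truth = truth,
         quantile_levels = quantile_levels,
         cdf_value_grid = cdf_value_grid,
         pmf_breaks = pmf_breaks, pmf_labels = pmf_labels,
         n_samples_per_model = as.integer(n_samples_per_model),
         seed = as.integer(seed)),
    class = "hub_spec"
  )
}

#' Generate component model outputs for a synthetic hub
#'
#' Emits, for each model and task, exact model output rows: the
#' distribution mean and median, quantiles at the spec's level grid, cdf
#' values at the declared value grid, pmf bin probabilities from the cut
#' points, and seeded pseudo-random sample draws. Sample draws can be
#' made joint across a subset of task IDs (`joint_across`): one uniform
#' is drawn per sample index and transformed through each task's quantile
#' function, creating genuine cross-task dependence within an index.
#'
#' @param spec A [hub_spec()] object.
#' @param output_types Subset of
#'   `c("mean", "median", "quantile", "cdf", "pmf", "sample")` to emit.
#' @param joint_across Optional task-ID names across which sample draws
#'   are joint (share a sample index).
#' @return A validated `model_output` table.
#' @export
generate_component_outputs <- function(spec,
                                       output_types = c("mean", "median",
                                                        "quantile", "cdf",
                                                        "pmf", "sample"),
                                       joint_across = NULL) {
  stopifnot(inherits(spec, "hub_spec"))
  output_types <- match.arg(output_types, several.ok = TRUE)
  tasks <- spec$tasks
  tid <- names(tasks)
  nt <- nrow(tasks)
  if ("cdf" %in% output_types && is.null(spec$cdf_value_grid)) {
    hub_error("hubpool_spec_error",
              "cdf output requested but spec has no cdf_value_grid")
  }
  if ("pmf" %in% output_types && is.null(spec$pmf_breaks)) {
    hub_error("hubpool_spec_error",
              "pmf output requested but spec has no pmf_breaks")
  }
  if (length(setdiff(joint_across, tid))) {
    hub_error("hubpool_spec_error",
              "joint_across must name task-ID columns")
  }
  set.seed(spec$seed)

  emit <- function(task_rows, otype, otid, value) {
    cbind(tasks[task_rows, , drop = FALSE],
          data.frame(output_type = otype, output_type_id = otid,
                     value = value, stringsAsFactors = FALSE))
  }

  pieces <- lapply(spec$models, function(m) {
    d <- make_dist(m$family, m, nt)
    rows <- list()
    t_all <- seq_len(nt)
    if ("mean" %in% output_types) {
      rows$mean <- emit(t_all, "mean", NA_character_, d$mean(t_all))
    }
    if ("median" %in% output_types) {
      rows$median <- emit(t_all, "median", NA_character_, d$median(t_all))
    }
    if ("quantile" %in% output_types) {
      lv <- spec$quantile_levels
      tt <- rep(t_all, each = length(lv))
      rows$quantile <- emit(tt, "quantile",
                            rep(canonical_otid(lv), nt),
                            d$q(rep(lv, nt), tt))
    }
    if ("cdf" %in% output_types) {
      xg <- sort(as.numeric(spec$cdf_value_grid))
      tt <- rep(t_all, each = length(xg))
      rows$cdf <- emit(tt, "cdf", rep(canonical_otid(xg), nt),
                       d$p(rep(xg, nt), tt))
    }
    if ("pmf" %in% output_types) {
      br <- spec$pmf_breaks
      nb <- length(br) + 1L
      probs <- vapply(t_all, function(t) {
        cp <- c(0, d$p(br, rep(t, length(br))), 1)
        diff(cp)
      }, numeric(nb))
      tt <- rep(t_all, each = nb)
      rows$pmf <- emit(tt, "pmf", rep(spec$pmf_labels, nt), as.vector(probs))
    }
    if ("sample" %in% output_types) {
      ns <- spec$n_samples_per_model
      if (length(joint_across)) {
        unit_cols <- setdiff(tid, joint_across)
        ukey <- group_key(tasks, unit_cols)
        samp <- lapply(split(t_all, ukey), function(tu) {
          u <- stats::runif(ns)
          tt <- rep(tu, each = ns)
          emit(tt, "sample",
               rep(as.character(seq_len(ns)), length(tu)),
               d$q(rep(u, length(tu)), tt))
        })
        rows$sample <- do.call(rbind, samp)
      } else {
        tt <- rep(t_all, each = ns)
        rows$sample <- emit(tt, "sample",
                            rep(as.character(seq_len(ns)), nt),
                            d$q(stats::runif(nt * ns), tt))
      }
    }
    out <- do.call(rbind, unname(rows))
    cbind(model_id = m$model_id, out)
  })

  out <- do.call(rbind, pieces)
  validate_model_output(out, task_id_names = tid,
                        pmf_category_order = spec$pmf_labels)
}

#' Generate a target series from a synthetic hub's truth distribution
#'
#' Draws one observation per task from the spec's truth distribution,
#' deterministically under the spec's seed (offset from the component
#' sample stream so forecasts and observations are independent draws).
#'
#' @param spec A [hub_spec()] object.
#' @return Data frame with the task-ID columns and an `observation`
#'   column; passes [validate_target_series()].
#' @export
generate_target_series <- function(spec) {
  stopifnot(inherits(spec, "hub_spec"))
  tasks <- spec$tasks
  nt <- nrow(tasks)
  d <- make_dist(spec$truth$family, spec$truth, nt)
  set.seed(spec$seed + 1L)
  u <- stats::runif(nt)
  out <- cbind(tasks, data.frame(observation = d$q(u, seq_len(nt))))
  validate_target_series(out)
}
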