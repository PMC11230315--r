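# Reconstruction of a predictive distribution from (level, value) pairs:
# shape-preserving monotone cubic spline through the CDF on the interior,
# location-scale parametric tails matched to the two most extreme pairs.

tail_families <- c("norm", "lnorm", "cauchy")

normalize_tail_dist <- function(tail_dist) {
  aliases <- c(norm = "norm", normal = "norm",
               lnorm = "lnorm", lognormal = "lnorm",
               cauchy = "cauchy")
  key <- aliases[tolower(tail_dist[1])]
  if (is.na(key)) {
    hub_error("hubpool_domain_error", paste0(
      "unknown tail_dist '", tail_dist[1],
      "'; must be one of norm, lnorm, cauchy"
    ))
  }
  unname(key)
}

# Standard quantile function of the unit member of each family; tails are
# location-scale transforms of these (lognormal: location-scale in log space).
tail_q_std <- function(family) {
  switch(family,
    norm = stats::qnorm,
    lnorm = stats::qnorm,
    cauchy = stats::qcauchy
  )
}

# Match location/scale so the tail passes through two (level, value) pairs.
fit_tail <- function(family, levels, values) {
  x <- if (family == "lnorm") log(values) else values
  z <- tail_q_std(family)(levels)
  scale <- (x[2] - x[1]) / (z[2] - z[1])
  loc <- x[1] - scale * z[1]
  list(loc = loc, scale = scale)
}

tail_cdf <- function(family, tail, x) {
  switch(family,
    norm = stats::pnorm(x, tail$loc, tail$scale),
    lnorm = ifelse(x <= 0, 0,
                   stats::pnorm((log(pmax(x, .Machine$double.xmin)) - tail$loc)
                                / tail$scale)),
    cauchy = stats::pcauchy(x, tail$loc, tail$scale)
  )
}

tail_quantile <- function(family, tail, theta) {
  switch(family,
    norm = stats::qnorm(theta, tail$loc, tail$scale),
    lnorm = exp(tail$loc + tail$scale * stats::qnorm(theta)),
    cauchy = stats::qcauchy(theta, tail$loc, tail$scale)
  )
}

#' Reconstruct a predictive distribution from quantile pairs
#'
#' Given a finite set of (quantile level, value) pairs from a predictive
#' distribution, builds an estimate of the full distribution: a monotone
#' (shape-preserving Hermite) cubic spline interpolates the CDF -- the
#' level as a function of the value -- between the smallest and largest
#' provided values, and parametric location-scale tails extend it beyond.
#' Each tail is matched exactly to the two most extreme pairs on its side
#' (lognormal tails are matched in log space and require strictly positive
#' values). Pairs with tied values but distinct levels are collapsed, with
#' a warning, to a single node at the mean of their levels.
#'
#' @param levels Numeric vector of quantile levels in (0, 1), strictly
#'   increasing.
#' @param values Numeric vector of the corresponding quantiles
#'   \eqn{F^{-1}(\theta)}, nondecreasing, same length as `levels`
#'   (at least 2).
#' @param tail_dist Parametric family for tail extrapolation: `"norm"`
#'   (default), `"lnorm"`, or `"cauchy"` (aliases `"normal"`,
#'   `"lognormal"` accepted).
#' @return An object of class `"quantile_distribution"` supporting
#'   [evaluate_cdf()], [evaluate_quantile()], and
#'   [quasi_random_samples()].
#' @examples
#' d <- fit_quantile_distribution(
#'   levels = c(0.1, 0.5, 0.9),
#'   values = qnorm(c(0.1, 0.5, 0.9), 100, 10)
#' )
#' evaluate_quantile(d, 0.5)
#' @export
fit_quantile_distribution <- function(levels, values,
                                      tail_dist = c("norm", "lnorm", "cauchy")) {
  family <- normalize_tail_dist(tail_dist)
  levels <- as.numeric(levels)
  values <- as.numeric(values)
  if (length(levels) != length(values)) {
    hub_error("hubpool_domain_error", "levels and values must have equal length")
  }
  if (length(levels) < 2) {
    hub_error("hubpool_insufficient_data_error",
              "at least 2 quantile pairs are required")
  }
  if (anyNA(levels) || anyNA(values) ||
      any(!is.finite(levels)) || any(!is.finite(values))) {
    hub_error("hubpool_domain_error", "levels and values must be finite")
  }
  if (any(levels <= 0 | levels >= 1)) {
    hub_error("hubpool_domain_error", "quantile levels must lie in (0, 1)")
  }
  if (is.unsorted(levels, strictly = TRUE)) {
    hub_error("hubpool_domain_error", "quantile levels must strictly increase")
  }
  if (is.unsorted(values)) {
    hub_error("hubpool_domain_error", "quantile values must be nondecreasing")
  }
  if (family == "lnorm" && any(values <= 0)) {
    hub_error("hubpool_support_error",
              "lognormal tails require strictly positive quantile values")
  }

  if (anyDuplicated(values)) {
    warning("tied quantile values collapsed to single CDF nodes ",
            "(flat region); levels averaged", call. = FALSE)
    grp <- match(values, values)
    levels <- as.numeric(tapply(levels, factor(grp, levels = unique(grp)), mean))
    values <- unique(values)
  }
  if (length(values) < 2) {
    hub_error("hubpool_insufficient_data_error",
              "fewer than 2 distinct quantile values after collapsing ties")
  }

  k <- length(values)
  lower <- fit_tail(family, levels[1:2], values[1:2])
  upper <- fit_tail(family, levels[c(k - 1, k)], values[c(k - 1, k)])
  interior <- stats::splinefun(values, levels, method = "monoH.FC")

  structure(
    list(levels = levels, values = values, family = family,
         lower = lower, upper = upper, interior = interior),
    class = "quantile_distribution"
  )
}

#' @export
print.quantile_distribution <- function(x, ...) {
  cat("<quantile_distribution> ", length(x$levels), " nodes on [",
      format(x$values[1]), ", ", format(x$values[length(x$values)]),
      "], ", x$family, " tails\n", sep = "")
  invisible(x)
}

#' Evaluate the reconstructed CDF
#'
#' Piecewise CDF of a fitted [fit_quantile_distribution()] object: the
#' lower parametric tail below the smallest provided quantile value, the
#' monotone spline on the interior, and the upper tail above the largest
#' value. Total over the reals, with limits 0 and 1.
#'
#' @param dist A `"quantile_distribution"` object.
#' @param x Numeric vector of evaluation points (may include `-Inf`/`Inf`).
#' @return Probabilities in \[0, 1\], same length as `x`.
#' @export
evaluate_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "quantile_distribution"))
  x <- as.numeric(x)
  v <- dist$values
  k <- length(v)
  out <- numeric(length(x))
  lo <- x < v[1]
  hi <- x > v[k]
  mid <- !lo & !hi & !is.na(x)
  if (any(lo)) out[lo] <- tail_cdf(dist$family, dist$lower, x[lo])
  if (any(hi)) out[hi] <- tail_cdf(dist$family, dist$upper, x[hi])
  if (any(mid)) {
    out[mid] <- pmin(pmax(dist$interior(x[mid]), dist$levels[1]),
                     dist$levels[k])
  }
  out[is.na(x)] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Evaluate the reconstructed quantile function
#'
#' Generalized inverse of [evaluate_cdf()]. Tail regions (below the
#' smallest / above the largest provided level) invert in closed form;
#' the spline interior is inverted by bisection to an absolute tolerance
#' of 1e-10 on the probability scale.
#'
#' @param dist A `"quantile_distribution"` object.
#' @param theta Numeric vector of probabilities, all in (0, 1).
#' @return Quantiles, same length as `theta`, nondecreasing in `theta`.
#' @export
evaluate_quantile <- function(dist, theta) {
  stopifnot(inherits(dist, "quantile_distribution"))
  theta <- as.numeric(theta)
  if (anyNA(theta) || any(theta <= 0 | theta >= 1)) {
    hub_error("hubpool_domain_error", "theta must lie strictly in (0, 1)")
  }
  lev <- dist$levels
  v <- dist$values
  k <- length(v)
  out <- numeric(length(theta))
  lo <- theta <= lev[1]
  hi <- theta >= lev[k]
  mid <- !lo & !hi
  if (any(lo)) out[lo] <- tail_quantile(dist$family, dist$lower, theta[lo])
  if (any(hi)) out[hi] <- tail_quantile(dist$family, dist$upper, theta[hi])
  if (any(mid)) {
    # vectorized bisection on the monotone interior spline
    t_mid <- theta[mid]
    a <- rep(v[1], length(t_mid))
    b <- rep(v[k], length(t_mid))
    # start from the bracketing input nodes to tighten the interval
    j <- findInterval(t_mid, lev)
    a <- v[j]
    b <- v[pmin(j + 1L, k)]
    for (iter in seq_len(200L)) {
      m <- (a + b) / 2
      fm <- dist$interior(m)
      left <- fm < t_mid
      a[left] <- m[left]
      b[!left] <- m[!left]
      if (max(abs(dist$interior((a + b) / 2) - t_mid)) < 1e-10 ||
          max(b - a) < 1e-13 * max(1, max(abs(v)))) break
    }
    out[mid] <- (a + b) / 2
  }
  out
}

#' Deterministic quasi-random samples from a reconstructed distribution
#'
#' Returns the quantiles of the distribution at the midpoint probability
#' grid \eqn{\theta_k = (k - 0.5)/n}, `k = 1..n`. Fully deterministic and
#' sorted ascending; used in place of Monte Carlo draws to remove sampling
#' noise from linear-pool computations.
#'
#' @param dist A `"quantile_distribution"` object.
#' @param n Positive integer number of samples.
#' @return Numeric vector of length `n`, sorted ascending.
#' @export
quasi_random_samples <- function(dist, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) {
    hub_error("hubpool_domain_error", "n must be a positive integer")
  }
  evaluate_quantile(dist, (seq_len(n) - 0.5) / n)
}
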