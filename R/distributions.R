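#' Build the probabilistic distribution for one parameter
#'
#' Families follow standard practice for decision-model inputs: beta for
#' probabilities, proportions and utilities; gamma for non-negative costs;
#' lognormal for relative risks; (truncated) normal for signed cost, utility
#' and QALY deltas; a point mass for degenerate ranges. Under the default
#' `ci95` interpretation the printed range is read as a central 95% interval:
#' moments are matched so that the distribution mean equals the resolved
#' base-case point and the 2.5%/97.5% quantiles approximate (low, high).
#' Under `minmax` the range is treated as the full support and a scaled beta
#' is fitted; this is also the fallback when beta moment matching is
#' infeasible (a warning is emitted).
#'
#' @param spec an `ahc_param_spec`.
#' @param interpretation `"ci95"`, `"minmax"` or `"point"` (degenerate
#'   distributions at the base case, useful for deterministic checks).
#' @return an object of class `ahc_distribution` with fields `family`,
#'   `parameters`, `support` and `mean`.
#' @export
build_distribution <- function(spec, interpretation = c("ci95", "minmax",
                                                        "point")) {
  interpretation <- match.arg(interpretation)
  m <- resolve_point(spec, "midpoint")
  lo <- spec$low
  hi <- spec$high

  point_mass <- function(v) dist_obj("point_mass", list(value = v), c(v, v), v)

  if (interpretation == "point" || (hi - lo) < .Machine$double.eps^0.5 &&
      is.null(spec$sd)) {
    return(point_mass(m))
  }
  s <- spec$sd %||% ((hi - lo) / (2 * stats::qnorm(0.975)))
  if (s <= 0) return(point_mass(m))

  scaled_beta <- function() {
    # range as support; concentration 4 keeps mass away from the endpoints
    mb <- (m - lo) / (hi - lo)
    mb <- min(max(mb, 1e-6), 1 - 1e-6)
    dist_obj("scaled_beta",
             list(shape1 = 4 * mb, shape2 = 4 * (1 - mb), low = lo, high = hi),
             c(lo, hi), m)
  }

  if (interpretation == "minmax") return(scaled_beta())

  switch(spec$category,
    probability = ,
    proportion = ,
    utility = {
      if (m <= 0 || m >= 1) return(point_mass(m))
      vmax <- m * (1 - m)
      if (s^2 >= vmax) {
        warning(sprintf(
          "parameter '%s': sd %.4g infeasible for beta with mean %.4g; shrunk",
          spec$name, s, m), call. = FALSE)
        s <- sqrt(0.95 * vmax)
      }
      nu <- vmax / s^2 - 1
      dist_obj("beta", list(shape1 = m * nu, shape2 = (1 - m) * nu),
               c(0, 1), m)
    },
    cost = {
      if (lo >= 0) {
        if (m <= 0) return(point_mass(m))
        dist_obj("gamma", list(shape = m^2 / s^2, rate = m / s^2),
                 c(0, Inf), m)
      } else {
        dist_obj("truncated_normal", list(mean = m, sd = s),
                 c(-Inf, Inf), m)
      }
    },
    relative_risk = {
      sdlog <- (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))
      dist_obj("lognormal",
               list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog),
               c(0, Inf), m)
    },
    probability_difference =
      dist_obj("truncated_normal", list(mean = m, sd = s), c(-1, 1), m),
    utility_delta = ,
    qaly_delta =
      dist_obj("truncated_normal", list(mean = m, sd = s), c(-Inf, Inf), m),
    resource_quantity = point_mass(m)
  )
}

dist_obj <- function(family, parameters, support, mean) {
  structure(list(family = family, parameters = parameters,
                 support = support, mean = mean),
            class = "ahc_distribution")
}

#' @export
print.ahc_distribution <- function(x, ...) {
  cat(sprintf("<%s mean=%.4g support=[%.4g, %.4g]>\n",
              x$family, x$mean, x$support[1], x$support[2]))
  invisible(x)
}

#' Draw from a fitted distribution
#'
#' Uses the R random number stream; seed management belongs to the caller.
#' Every family consumes exactly one uniform-equivalent draw per variate so
#' that draw sequences stay aligned across runs.
#'
#' @param dist an `ahc_distribution`.
#' @param n number of draws.
#' @return numeric vector of length `n`, always inside the support.
#' @export
sample_distribution <- function(dist, n = 1L) {
  p <- dist$parameters
  switch(dist$family,
    point_mass = rep(p$value, n),
    beta = stats::rbeta(n, p$shape1, p$shape2),
    scaled_beta = p$low + (p$high - p$low) * stats::rbeta(n, p$shape1, p$shape2),
    gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    truncated_normal = {
      a <- stats::pnorm(dist$support[1], p$mean, p$sd)
      b <- stats::pnorm(dist$support[2], p$mean, p$sd)
      stats::qnorm(a + (b - a) * stats::runif(n), p$mean, p$sd)
    },
    stop_ahc("unknown distribution family '%s'", dist$family)
  )
}

#' Distribution quantiles (used to verify the ci95 fit)
#' @inheritParams sample_distribution
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
quantile_distribution <- function(dist, probs) {
  p <- dist$parameters
  switch(dist$family,
    point_mass = rep(p$value, length(probs)),
    beta = stats::qbeta(probs, p$shape1, p$shape2),
    scaled_beta = p$low + (p$high - p$low) * stats::qbeta(probs, p$shape1, p$shape2),
    gamma = stats::qgamma(probs, shape = p$shape, rate = p$rate),
    lognormal = stats::qlnorm(probs, p$meanlog, p$sdlog),
    truncated_normal = {
      a <- stats::pnorm(dist$support[1], p$mean, p$sd)
      b <- stats::pnorm(dist$support[2], p$mean, p$sd)
      stats::qnorm(a + (b - a) * probs, p$mean, p$sd)
    }
  )
}

#' Fit distributions for every parameter in a set
#'
#' @param pset an `ahc_parameter_set`.
#' @inheritParams build_distribution
#' @return named list of `ahc_distribution` objects, in entry order.
#' @export
param_distributions <- function(pset, interpretation = "ci95") {
  lapply(pset$entries, build_distribution, interpretation = interpretation)
}

#' Draw one joint parameter sample
#'
#' Draws each parameter independently from its fitted distribution (the
#' evidence base states no correlation structure). Deterministic given the
#' RNG state: seed before calling.
#'
#' @param dists named list from [param_distributions()].
#' @return named numeric vector, one value per parameter.
#' @export
sample_parameters <- function(dists) {
  vapply(dists, sample_distribution, numeric(1))
}
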