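#' Synthetic Gompertz life table
#'
#' Generates an annual life table with Gompertz mortality,
#' `qx(age) = 1 - exp(-a * exp(b * age))`, capped at 1 at the terminal age.
#' The defaults are calibrated so that period life expectancy at birth is
#' about 81 years — England-like general-population mortality — before any
#' intellectual-disability adjustment, so analyses run without external
#' mortality downloads.
#'
#' @param a baseline annual hazard at age 0 (positive).
#' @param b log-hazard slope per year of age (non-negative).
#' @param max_age terminal age; `qx` there is set to 1.
#' @return an [life_table()] over ages `0:max_age`.
#' @export
gompertz_life_table <- function(a = 3.584035e-05, b = 0.09, max_age = 100L) {
  if (!is_number(a) || a <= 0) stop_ahc("'a' must be positive")
  if (!is_number(b) || b < 0) stop_ahc("'b' must be non-negative")
  ages <- 0:max_age
  qx <- 1 - exp(-a * exp(b * ages))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' @rdname gompertz_life_table
#' @export
default_life_table <- function() gompertz_life_table()

#' Packaged parameter fixture
#'
#' Loads the parameter registry shipped with the package: every printed
#' model input (incidence probabilities by age band, unit costs,
#' effectiveness cascades, utilities and lifetime deltas) plus the handful
#' of documented placeholder assumptions, each entry tagged with its
#' provenance. The fixture validates against [load_parameter_set()] and
#' covers every name any condition model resolves.
#'
#' @return an `ahc_parameter_set`.
#' @export
ahc_parameter_fixture <- function() {
  path <- system.file("extdata", "ahc_parameters.yaml", package = "ahcmodel",
                      mustWork = TRUE)
  read_parameter_set(path)
}

#' Random structurally-valid parameter scenario
#'
#' Generates a parameter set with the same entry structure as the packaged
#' fixture but randomised values: probabilities and utilities anywhere in
#' their supports, costs up to twice the fixture's upper bound, occasional
#' degenerate point ranges. Useful for property tests that the pipeline
#' accepts any valid configuration. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param p_degenerate probability an entry collapses to a point range.
#' @return an `ahc_parameter_set`.
#' @export
random_scenario <- function(seed, p_degenerate = 0.1) {
  tmpl <- ahc_parameter_fixture()
  set.seed(seed)
  entries <- lapply(tmpl$entries, function(e) {
    rng <- switch(e$category,
      probability = ,
      proportion = sort(stats::runif(2)),
      utility = sort(stats::runif(2)),
      cost = {
        top <- 2 * max(abs(e$high), 10)
        if (e$low < 0) sort(stats::runif(2, -top, top))
        else sort(stats::runif(2, 0, top))
      },
      relative_risk = sort(stats::runif(2, 0.3, 5)),
      probability_difference = sort(stats::runif(2, -0.2, 0.2)),
      utility_delta = sort(stats::runif(2, -0.2, 0.2)),
      qaly_delta = sort(stats::runif(2, -1, 1)),
      resource_quantity = c(e$low, e$high)
    )
    if (stats::runif(1) < p_degenerate) rng[2] <- rng[1]
    e$low <- rng[1]
    e$high <- rng[2]
    e$point <- if (!is.null(e$point)) mean(rng) else NULL
    e$sd <- NULL
    e
  })
  # the ID mortality multiplier must stay a sensible positive factor
  m <- entries[["global.id_mortality_multiplier"]]
  m$low <- m$high <- m$point <- stats::runif(1, 1, 5)
  entries[["global.id_mortality_multiplier"]] <- m
  parameter_set(entries, tmpl$metadata)
}
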