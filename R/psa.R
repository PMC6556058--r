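#' Evaluate the full strategy for one parameter map
#'
#' Runs every condition model with the supplied parameter map, computes the
#' intervention cost annuity on the ID-adjusted survival curve and
#' aggregates. This is the unit of work behind both the deterministic base
#' case and each probabilistic draw.
#'
#' @param params named parameter map (a draw or resolved base case).
#' @param pset the `ahc_parameter_set` (for the intervention components and
#'   discount rate).
#' @param lt an unadjusted [life_table()]; the ID mortality multiplier from
#'   `params` is applied here.
#' @param yearly_cost_override optional yearly intervention cost, GBP,
#'   replacing the component build-up (used by the one-way sensitivity
#'   analysis of the intervention cost).
#' @param age_cap terminal age.
#' @return an `ahc_strategy_result`.
#' @export
evaluate_strategy <- function(params, pset, lt, yearly_cost_override = NULL,
                              age_cap = NULL) {
  r <- pset$metadata$discount_rate
  age_cap <- age_cap %||% pset$metadata$age_cap
  lt_adj <- adjust_id_mortality(lt, pget(params, "global.id_mortality_multiplier"))
  surv <- survival_curve(lt_adj, 40, age_cap)
  yearly <- yearly_cost_override %||%
    intervention_yearly_cost(intervention_components(pset))
  ipv <- intervention_cost_pv(yearly, surv, r)
  res <- evaluate_all_conditions(params, lt_adj, discount_rate = r,
                                 age_cap = age_cap)
  aggregate_strategy(res, ipv)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every parameter from its fitted distribution, evaluates all
#' condition models and the intervention annuity with that single joint
#' draw, and summarises incremental costs, QALYs and cost-effectiveness
#' across draws. Fully reproducible given `seed`: per-draw sub-seeds are
#' derived from the root seed by counter, so any draw can be reproduced in
#' isolation.
#'
#' @param pset an `ahc_parameter_set`.
#' @param lt an unadjusted [life_table()] (default: the packaged synthetic
#'   England-like Gompertz table).
#' @param n_draws number of Monte Carlo draws.
#' @param seed root seed.
#' @param thresholds willingness-to-pay thresholds for the CEAC.
#' @param interpretation range interpretation for [build_distribution()].
#' @param yearly_cost_override,param_overrides fixed values imposed after
#'   sampling: a yearly intervention cost, and/or a named vector of
#'   parameter values. Because overrides are applied after the joint draw,
#'   runs with the same seed share common random numbers.
#' @param age_cap terminal age.
#' @return an `ahc_psa` object: `draws` (data frame with one row per draw:
#'   `draw`, `inc_cost`, `inc_qaly`, `icer`, `flag`), `summary` (means, SDs,
#'   2.5%/97.5% percentiles, mean of finite per-draw ICERs with the excluded
#'   count, ratio-of-means ICER, CEAC points) and run metadata.
#' @export
run_psa <- function(pset, lt = default_life_table(), n_draws = 1000,
                    seed = 1, thresholds = c(20000, 30000),
                    interpretation = "ci95", yearly_cost_override = NULL,
                    param_overrides = NULL, age_cap = NULL) {
  if (n_draws < 1) stop_ahc("n_draws must be at least 1")
  dists <- param_distributions(pset, interpretation)
  set.seed(seed)
  draw_seeds <- sample.int(2147483646L, n_draws)
  inc_cost <- numeric(n_draws)
  inc_qaly <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(draw_seeds[i])
    p <- sample_parameters(dists)
    if (!is.null(param_overrides)) {
      unknown <- setdiff(names(param_overrides), names(p))
      if (length(unknown)) {
        stop_ahc("unknown parameter override(s): %s",
                 paste(unknown, collapse = ", "))
      }
      p[names(param_overrides)] <- param_overrides
    }
    s <- tryCatch(
      evaluate_strategy(p, pset, lt, yearly_cost_override, age_cap),
      error = function(e) {
        stop_ahc("PSA draw %d failed: %s\nparameters: %s", i,
                 conditionMessage(e),
                 paste(sprintf("%s=%.6g", names(p), p), collapse = ", "))
      })
    inc_cost[i] <- s$inc_cost_total
    inc_qaly[i] <- s$inc_qaly_total
  }
  icers <- ifelse(inc_qaly > 0, inc_cost / inc_qaly, NA_real_)
  flags <- vapply(seq_len(n_draws), function(i) {
    icer(inc_cost[i], inc_qaly[i])$flag
  }, character(1))
  draws <- data.frame(draw = seq_len(n_draws), inc_cost = inc_cost,
                      inc_qaly = inc_qaly, icer = icers, flag = flags)
  structure(
    list(draws = draws,
         summary = summarise_psa(draws, thresholds),
         seed = seed, n_draws = n_draws, thresholds = thresholds,
         interpretation = interpretation),
    class = "ahc_psa"
  )
}

summarise_psa <- function(draws, thresholds) {
  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  finite <- is.finite(draws$icer)
  list(
    n_draws = nrow(draws),
    mean_inc_cost = mean(draws$inc_cost),
    sd_inc_cost = stats::sd(draws$inc_cost),
    ci_inc_cost = pct(draws$inc_cost),
    mean_inc_qaly = mean(draws$inc_qaly),
    sd_inc_qaly = stats::sd(draws$inc_qaly),
    ci_inc_qaly = pct(draws$inc_qaly),
    mean_icer = mean(draws$icer[finite]),
    ci_icer = if (any(finite)) pct(draws$icer[finite]) else c(NA_real_, NA_real_),
    icer_excluded = sum(!finite),
    icer_ratio_of_means = if (mean(draws$inc_qaly) != 0) {
      mean(draws$inc_cost) / mean(draws$inc_qaly)
    } else NA_real_,
    ceac = ceac(draws, thresholds)
  )
}

#' @export
print.ahc_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<ahc_psa: %d draws, seed %s>\n",
    "  inc cost  %9.2f (SD %.2f, 95%% %.2f-%.2f)\n",
    "  inc QALY  %9.4f (SD %.4f, 95%% %.4f-%.4f)\n",
    "  mean ICER %9.2f (95%% %.2f-%.2f, %d draws excluded)\n",
    "  ratio-of-means ICER %.2f\n"),
    x$n_draws, format(x$seed),
    s$mean_inc_cost, s$sd_inc_cost, s$ci_inc_cost[1], s$ci_inc_cost[2],
    s$mean_inc_qaly, s$sd_inc_qaly, s$ci_inc_qaly[1], s$ci_inc_qaly[2],
    s$mean_icer, s$ci_icer[1], s$ci_icer[2], s$icer_excluded,
    s$icer_ratio_of_means))
  for (i in seq_len(nrow(s$ceac))) {
    cat(sprintf("  P(cost-effective at %6.0f GBP/QALY) = %.3f\n",
                s$ceac$threshold[i], s$ceac$probability[i]))
  }
  invisible(x)
}

#' One-way sensitivity analysis
#'
#' Re-runs the PSA for each value of one parameter, holding all other
#' parameters at their probabilistic distributions and reusing the same
#' root seed (common random numbers), so differences between rows are due
#' to the varied parameter alone. The special name
#' `"intervention.yearly_cost"` varies the yearly intervention cost instead
#' of a sampled parameter.
#'
#' @inheritParams run_psa
#' @param parameter_name parameter to vary.
#' @param values values to impose, one row each.
#' @return data frame with one row per value: mean incremental cost/QALYs,
#'   mean and 95% percentile interval of per-draw ICERs, and the
#'   probability of cost-effectiveness at each threshold.
#' @export
one_way_sa <- function(pset, lt = default_life_table(), parameter_name,
                       values, n_draws = 1000, seed = 1,
                       thresholds = c(20000, 30000), interpretation = "ci95") {
  if (!length(values)) stop_ahc("'values' must be non-empty")
  special <- identical(parameter_name, "intervention.yearly_cost")
  if (!special && !parameter_name %in% names(pset$entries)) {
    stop_ahc("unknown parameter '%s'", parameter_name)
  }
  rows <- lapply(values, function(v) {
    psa <- if (special) {
      run_psa(pset, lt, n_draws, seed, thresholds, interpretation,
              yearly_cost_override = v)
    } else {
      run_psa(pset, lt, n_draws, seed, thresholds, interpretation,
              param_overrides = stats::setNames(v, parameter_name))
    }
    s <- psa$summary
    out <- data.frame(value = v, mean_inc_cost = s$mean_inc_cost,
                      mean_inc_qaly = s$mean_inc_qaly,
                      mean_icer = s$mean_icer,
                      icer_lo = s$ci_icer[1], icer_hi = s$ci_icer[2])
    for (i in seq_along(thresholds)) {
      out[[sprintf("p_ce_%g", thresholds[i])]] <- s$ceac$probability[i]
    }
    out
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness plane coordinates
#'
#' @param psa an `ahc_psa` object.
#' @return data frame `(inc_qaly, inc_cost)`, one row per draw in draw
#'   order, ready for scatter plotting.
#' @export
ce_plane <- function(psa) {
  if (!inherits(psa, "ahc_psa")) stop_ahc("ce_plane expects an ahc_psa object")
  if (!nrow(psa$draws)) stop_ahc("empty draw set")
  psa$draws[, c("inc_qaly", "inc_cost")]
}
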