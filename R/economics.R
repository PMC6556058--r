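#' Yearly cost of one annual health check
#'
#' Builds the per-person yearly intervention cost from staff-time
#' components. Each component is `minutes` of a role's time at a
#' `rate_per_hour` unit cost; component costs are rounded to the nearest
#' pound before summation (20 min of GP time at GBP 216/h is GBP 72, 5 min
#' of social-worker time at GBP 79/h is GBP 6.58, booked as GBP 7).
#'
#' @param components data frame with columns `role`, `minutes`,
#'   `rate_per_hour` (see [intervention_components()]).
#' @return total yearly cost in GBP (whole pounds).
#' @export
intervention_yearly_cost <- function(components) {
  req <- c("minutes", "rate_per_hour")
  if (!all(req %in% names(components))) {
    stop_ahc("components need columns 'minutes' and 'rate_per_hour'")
  }
  if (any(components$minutes < 0) || any(components$rate_per_hour < 0)) {
    stop_ahc("negative quantities in intervention components")
  }
  sum(round(components$minutes / 60 * components$rate_per_hour))
}

#' Staff-time components of the health check
#'
#' @param pset an `ahc_parameter_set` whose metadata carries
#'   `intervention_components`.
#' @return data frame with columns `role`, `minutes`, `rate_per_hour`.
#' @export
intervention_components <- function(pset) {
  ic <- pset$metadata$intervention_components
  if (is.null(ic)) stop_ahc("parameter set has no intervention components")
  ic
}

#' Present value of the lifetime intervention cost
#'
#' The yearly cost is paid while alive from age 40, half-cycle-corrected
#' with the same trapezoidal survival averaging as the Markov engine, and
#' discounted to age 40.
#'
#' @param yearly_cost cost per person-year, GBP.
#' @param surv an [survival_curve()] starting at age 40 (ID-adjusted).
#' @param rate annual discount rate.
#' @return present value in GBP.
#' @export
intervention_cost_pv <- function(yearly_cost, surv, rate = 0.035) {
  s <- surv$values
  K <- length(s) - 1L
  stream <- yearly_cost * (s[seq_len(K)] + s[seq_len(K) + 1L]) / 2
  present_value(stream, rate, offset_years = 0)
}

#' Aggregate per-condition increments into a strategy result
#'
#' @param condition_results list of `ahc_condition_result` objects.
#' @param intervention_pv present value of the intervention cost, GBP.
#' @return an `ahc_strategy_result` with `inc_cost_total` (intervention plus
#'   summed condition cost increments), `inc_qaly_total`, `intervention_pv`
#'   and the per-condition list. Order-independent.
#' @export
aggregate_strategy <- function(condition_results, intervention_pv) {
  tags <- vapply(condition_results, function(x) x$condition, character(1))
  if (anyDuplicated(tags)) {
    stop_ahc("duplicate condition tags: %s",
             paste(unique(tags[duplicated(tags)]), collapse = ", "))
  }
  inc_cost <- sum(vapply(condition_results, function(x) x$inc_cost, numeric(1)))
  inc_qaly <- sum(vapply(condition_results, function(x) x$inc_qaly, numeric(1)))
  structure(
    list(inc_cost_total = intervention_pv + inc_cost,
         inc_qaly_total = inc_qaly,
         intervention_pv = intervention_pv,
         per_condition = condition_results[order(tags)]),
    class = "ahc_strategy_result"
  )
}

#' @export
print.ahc_strategy_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<ahc_strategy_result>\n  incremental cost:  %10.2f GBP",
    " (intervention %.2f)\n  incremental QALYs: %10.4f\n"),
    x$inc_cost_total, x$intervention_pv, x$inc_qaly_total))
  invisible(x)
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' Dominance is reported through flags rather than errors so that
#' probabilistic draws never abort a run: `"ok"` (positive QALY gain),
#' `"dominant"` (cheaper and more effective; the negative ratio is
#' returned), `"dominated"` (costlier, no QALY gain; ratio `NA`),
#' `"undefined"` (no difference in either dimension).
#'
#' @param inc_cost,inc_qaly incremental cost (GBP) and QALYs.
#' @return list with `value` and `flag`.
#' @export
icer <- function(inc_cost, inc_qaly) {
  if (inc_cost == 0 && inc_qaly == 0) {
    return(list(value = NA_real_, flag = "undefined"))
  }
  if (inc_qaly > 0) {
    return(list(value = inc_cost / inc_qaly,
                flag = if (inc_cost < 0) "dominant" else "ok"))
  }
  if (inc_cost > 0) return(list(value = NA_real_, flag = "dominated"))
  list(value = NA_real_, flag = "undefined")
}

#' Net monetary benefit
#'
#' @param inc_cost,inc_qaly incremental cost and QALYs.
#' @param threshold willingness to pay per QALY, GBP.
#' @return `threshold * inc_qaly - inc_cost`, GBP.
#' @export
nmb <- function(inc_cost, inc_qaly, threshold) {
  if (any(threshold < 0)) stop_ahc("threshold must be non-negative")
  threshold * inc_qaly - inc_cost
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws data frame with columns `inc_cost` and `inc_qaly`, one row
#'   per probabilistic draw.
#' @param thresholds willingness-to-pay values, GBP per QALY.
#' @return data frame `(threshold, probability)` where probability is the
#'   fraction of draws with positive net monetary benefit.
#' @export
ceac <- function(draws, thresholds = c(20000, 30000)) {
  if (!nrow(draws)) stop_ahc("empty draw set")
  probs <- vapply(thresholds, function(th) {
    mean(nmb(draws$inc_cost, draws$inc_qaly, th) > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = probs)
}
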