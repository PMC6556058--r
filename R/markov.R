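#' Annual-cycle cohort Markov model
#'
#' The engine is deliberately generic: a model is a state list, a
#' transition rule returning one row-stochastic matrix per age, and per-state
#' annual rewards. Residual probability is never normalised silently — every
#' row must sum to one within `1e-9` or the run aborts naming the age and
#' state, so specification errors surface instead of being absorbed.
#'
#' @param states ordered character vector of state labels.
#' @param transition_rule `function(age, params)` returning a
#'   `length(states)` square matrix with rows/columns in state order.
#' @param cost,utility per-state annual rewards: a named numeric vector, or
#'   a `function(age)` returning one, evaluated each cycle.
#' @param start_age cohort starting age in years.
#' @param initial_occupancy occupancy vector summing to 1; defaults to
#'   everyone in the first state.
#' @param entry_cost optional per-state one-off cost charged to new entrants
#'   at the cycle of transition (used for diagnosis and screening work-ups);
#'   vector or `function(age)`.
#' @param absorbing labels of absorbing death states (self-transition 1).
#' @return an object of class `ahc_markov_model`.
#' @export
markov_model <- function(states, transition_rule, cost, utility, start_age,
                         initial_occupancy = NULL, entry_cost = NULL,
                         absorbing = "dead") {
  if (anyDuplicated(states)) stop_ahc("duplicate state labels")
  if (!all(absorbing %in% states)) stop_ahc("absorbing states not in state list")
  if (is.null(initial_occupancy)) {
    initial_occupancy <- stats::setNames(c(1, rep(0, length(states) - 1L)), states)
  }
  if (abs(sum(initial_occupancy) - 1) > 1e-9) {
    stop_ahc("initial occupancy must sum to 1")
  }
  structure(
    list(states = states, transition_rule = transition_rule, cost = cost,
         utility = utility, start_age = start_age,
         initial_occupancy = initial_occupancy, entry_cost = entry_cost,
         absorbing = absorbing),
    class = "ahc_markov_model"
  )
}

#' @export
print.ahc_markov_model <- function(x, ...) {
  cat(sprintf("<ahc_markov_model: %d states, start age %d>\n  states: %s\n",
              length(x$states), x$start_age, paste(x$states, collapse = ", ")))
  invisible(x)
}

check_matrix <- function(P, states, age) {
  n <- length(states)
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n) {
    stop_ahc("transition matrix at age %d has wrong dimensions", age)
  }
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) {
    bad <- states[which(apply(P < -1e-12 | P > 1 + 1e-12, 1, any))[1]]
    stop_ahc("transition probability outside [0,1] for state '%s' at age %d",
             bad, age)
  }
  rs <- rowSums(P)
  off <- which(abs(rs - 1) > 1e-9)
  if (length(off)) {
    stop_ahc("transition row for state '%s' at age %d sums to %.12f, not 1",
             states[off[1]], age, rs[off[1]])
  }
  invisible(P)
}

#' Run a cohort through a Markov model
#'
#' Propagates state occupancy from `start_age` to `age_cap` one annual cycle
#' at a time, recording both occupancy and the flow of new entrants into
#' each state (needed for one-off transition costs).
#'
#' @param model an [markov_model()].
#' @param params parameter map forwarded to the transition rule.
#' @param age_cap final age; the trace has `age_cap - start_age` cycles.
#' @return an `ahc_cohort_trace`: `occupancy` ((cycles+1) x states),
#'   `entrants` (cycles x states), `states`, `ages`, `start_age`.
#' @export
run_cohort <- function(model, params = NULL, age_cap = 100) {
  K <- age_cap - model$start_age
  if (K < 1) stop_ahc("age_cap must exceed the model start age")
  n <- length(model$states)
  occ <- matrix(0, K + 1, n, dimnames = list(NULL, model$states))
  ent <- matrix(0, K, n, dimnames = list(NULL, model$states))
  occ[1, ] <- model$initial_occupancy[model$states]
  for (k in seq_len(K)) {
    age <- model$start_age + k - 1L
    P <- check_matrix(model$transition_rule(age, params), model$states, age)
    for (a in model$absorbing) {
      if (abs(P[a, a] - 1) > 1e-12) {
        stop_ahc("absorbing state '%s' not absorbing at age %d", a, age)
      }
    }
    occ[k + 1, ] <- occ[k, ] %*% P
    Poff <- P
    diag(Poff) <- 0
    ent[k, ] <- occ[k, ] %*% Poff
  }
  structure(
    list(occupancy = occ, entrants = ent, states = model$states,
         start_age = model$start_age, ages = model$start_age:age_cap),
    class = "ahc_cohort_trace"
  )
}

#' @export
print.ahc_cohort_trace <- function(x, ...) {
  cat(sprintf("<ahc_cohort_trace: %d cycles from age %d, %d states>\n",
              nrow(x$occupancy) - 1L, x$start_age, length(x$states)))
  invisible(x)
}

reward_matrix <- function(reward, trace) {
  K <- nrow(x = trace$occupancy) - 1L
  n <- length(trace$states)
  if (is.null(reward)) return(matrix(0, K, n))
  if (is.function(reward)) {
    m <- t(vapply(trace$ages[seq_len(K)],
                  function(a) reward(a)[trace$states], numeric(n)))
  } else if (is.matrix(reward)) {
    m <- reward
  } else {
    m <- matrix(rep(reward[trace$states], each = K), K, n)
  }
  if (anyNA(m)) stop_ahc("reward not defined for every state")
  m
}

#' Accrue half-cycle-corrected rewards along a trace
#'
#' Per-cycle accrual is the reward dotted with the trapezoidal average of
#' the occupancy at the start and end of the cycle (the half-cycle
#' correction); one-off entry costs are charged to new entrants at the cycle
#' of transition, without averaging.
#'
#' @param trace an `ahc_cohort_trace`.
#' @param cost,utility,entry_cost as in [markov_model()].
#' @return list with `cost_stream` and `qaly_stream`, one value per cycle.
#' @export
accrue_rewards <- function(trace, cost, utility, entry_cost = NULL) {
  K <- nrow(trace$occupancy) - 1L
  mid <- (trace$occupancy[seq_len(K), , drop = FALSE] +
          trace$occupancy[seq_len(K) + 1L, , drop = FALSE]) / 2
  cost_stream <- rowSums(mid * reward_matrix(cost, trace))
  qaly_stream <- rowSums(mid * reward_matrix(utility, trace))
  if (!is.null(entry_cost)) {
    cost_stream <- cost_stream +
      rowSums(trace$entrants * reward_matrix(entry_cost, trace))
  }
  list(cost_stream = cost_stream, qaly_stream = qaly_stream)
}

#' Present value of a per-cycle stream
#'
#' Discounts cycle `k` (0-based) at `(1 + rate)^-(k + offset_years)`. All
#' condition models discount to the common base age of 40, so a model
#' starting at age 50 carries `offset_years = 10`.
#'
#' @param stream numeric per-cycle values.
#' @param rate annual discount rate in `[0, 1)`.
#' @param offset_years delay of the stream's first cycle from the base age.
#' @return a single number.
#' @export
present_value <- function(stream, rate = 0.035, offset_years = 0) {
  if (rate < 0 || rate >= 1) stop_ahc("rate must lie in [0, 1)")
  if (offset_years < 0) stop_ahc("offset_years must be non-negative")
  if (!length(stream)) return(0)
  k <- seq_along(stream) - 1
  sum(stream / (1 + rate)^(k + offset_years))
}

#' Export a cohort trace as a data frame (one row per cycle)
#'
#' @param trace an `ahc_cohort_trace`.
#' @param streams optional result of [accrue_rewards()] to append.
#' @return data frame with cycle, age and per-state occupancy columns.
#' @export
trace_table <- function(trace, streams = NULL) {
  K <- nrow(trace$occupancy) - 1L
  df <- data.frame(cycle = 0:K, age = trace$ages,
                   trace$occupancy, check.names = FALSE)
  if (!is.null(streams)) {
    df$cost <- c(streams$cost_stream, NA)
    df$qaly <- c(streams$qaly_stream, NA)
  }
  df
}
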