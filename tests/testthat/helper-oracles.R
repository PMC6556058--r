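# Independent oracles used across the suite.

# Count-based micro-simulation of a cohort through the model's own
# transition matrices: stochastic propagation of individuals (multinomial
# counts per state and cycle), independent of the deterministic
# matrix-product engine it checks.
simulate_cohort_counts <- function(model, age_cap, n_individuals,
                                   params = NULL) {
  states <- model$states
  K <- age_cap - model$start_age
  counts <- matrix(0, K + 1, length(states), dimnames = list(NULL, states))
  counts[1, ] <- stats::rmultinom(1, n_individuals,
                                  model$initial_occupancy[states])[, 1]
  for (k in seq_len(K)) {
    P <- model$transition_rule(model$start_age + k - 1L, params)
    nxt <- numeric(length(states))
    for (i in seq_along(states)) {
      if (counts[k, i] > 0) {
        nxt <- nxt + stats::rmultinom(1, counts[k, i], P[i, ])[, 1]
      }
    }
    counts[k + 1, ] <- nxt
  }
  counts / n_individuals
}

# binomial standard error for an occupancy proportion
occ_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

# random small cohort model with one absorbing death state and a constant
# row-stochastic transition matrix
random_markov_model <- function(n_states, start_age = 40L) {
  states <- c(paste0("s", seq_len(n_states - 1L)), "dead")
  P <- matrix(stats::rgamma(n_states^2, 1), n_states)
  P <- P / rowSums(P)
  P[n_states, ] <- c(rep(0, n_states - 1L), 1)
  dimnames(P) <- list(states, states)
  init <- stats::rgamma(n_states - 1L, 1)
  init <- stats::setNames(c(init / sum(init), 0), states)
  markov_model(
    states,
    transition_rule = function(age, params) P,
    cost = stats::setNames(c(stats::runif(n_states - 1L, 0, 1000), 0), states),
    utility = stats::setNames(c(stats::runif(n_states - 1L), 0), states),
    start_age = start_age,
    initial_occupancy = init
  )
}

# toy two-state life table / model used by several closed-form checks
two_state_model <- function(q = 0.5, start_age = 40L) {
  states <- c("alive", "dead")
  P <- matrix(c(1 - q, q, 0, 1), 2, byrow = TRUE,
              dimnames = list(states, states))
  markov_model(states, function(age, params) P,
               cost = c(alive = 0, dead = 0),
               utility = c(alive = 1, dead = 0),
               start_age = start_age)
}

# shared heavyweight acceptance runs (computed once per session)
acceptance_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$runs)) {
      pset <- ahc_parameter_fixture()
      t0 <- proc.time()[["elapsed"]]
      psa <- run_psa(pset, n_draws = 1000, seed = 1)
      owsa50 <- one_way_sa(pset, parameter_name = "intervention.yearly_cost",
                           values = 50, n_draws = 1000, seed = 1)
      env$runs <- list(pset = pset, psa = psa, owsa50 = owsa50,
                       elapsed = proc.time()[["elapsed"]] - t0)
    }
    env$runs
  }
})
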