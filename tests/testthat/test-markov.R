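test_that("two-state cohort follows the closed form", {
  m <- two_state_model(q = 0.5)
  tr <- run_cohort(m, age_cap = 42)
  expect_equal(unname(tr$occupancy),
               matrix(c(1, 0, 0.5, 0.5, 0.25, 0.75), 3, byrow = TRUE))
  st <- accrue_rewards(tr, m$cost, m$utility)
  # trapezoid on survival (1, 0.5, 0.25)
  expect_equal(st$qaly_stream, c(0.75, 0.375))
  expect_equal(st$cost_stream, c(0, 0))
})

test_that("identity transitions leave occupancy constant", {
  states <- c("a", "b", "dead")
  I3 <- diag(3)
  dimnames(I3) <- list(states, states)
  m <- markov_model(states, function(age, params) I3,
                    cost = c(a = 1, b = 2, dead = 0),
                    utility = c(a = 0.5, b = 0.6, dead = 0),
                    start_age = 40L,
                    initial_occupancy = c(a = 0.3, b = 0.7, dead = 0))
  tr <- run_cohort(m, age_cap = 50)
  expect_true(all(apply(tr$occupancy, 1,
                        function(r) identical(r, tr$occupancy[1, ]))))
  st <- accrue_rewards(tr, m$cost, m$utility)
  expect_equal(st$cost_stream, rep(0.3 * 1 + 0.7 * 2, 10))
})

test_that("invalid transition rows fail naming age and state", {
  states <- c("a", "dead")
  bad <- markov_model(states, function(age, params) {
    matrix(c(0.6, 0.3, 0, 1), 2, byrow = TRUE,
           dimnames = list(states, states))
  }, cost = c(a = 0, dead = 0), utility = c(a = 1, dead = 0),
  start_age = 40L)
  expect_error(run_cohort(bad, age_cap = 45), "state 'a' at age 40")

  notabs <- markov_model(states, function(age, params) {
    matrix(c(0.5, 0.5, 0.1, 0.9), 2, byrow = TRUE,
           dimnames = list(states, states))
  }, cost = c(a = 0, dead = 0), utility = c(a = 1, dead = 0),
  start_age = 40L)
  expect_error(run_cohort(notabs, age_cap = 45), "not absorbing")
})

test_that("occupancy conserves probability over 60 cycles", {
  set.seed(11)
  for (n_states in 3:5) {
    m <- random_markov_model(n_states)
    tr <- run_cohort(m, age_cap = 100)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) <= 1e-9))
    # death occupancy is non-decreasing
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
})

test_that("cohort traces match a 200k-individual micro-simulation", {
  set.seed(31)
  n <- 200000
  for (n_states in 3:5) {
    m <- random_markov_model(n_states)
    tr <- run_cohort(m, age_cap = 60)
    sim <- simulate_cohort_counts(m, 60, n)
    se <- occ_se(tr$occupancy, n)
    expect_true(all(abs(sim - tr$occupancy) <= 3 * se + 1e-9),
                info = paste(n_states, "states"))
    # half-cycle-corrected accruals agree when computed on either trace
    eng <- accrue_rewards(tr, m$cost, m$utility)
    simtr <- tr
    simtr$occupancy <- sim
    simacc <- accrue_rewards(simtr, m$cost, m$utility)
    expect_equal(sum(simacc$qaly_stream), sum(eng$qaly_stream),
                 tolerance = 0.01)
  }
})

test_that("entry costs charge new entrants at the transition cycle", {
  states <- c("a", "b", "dead")
  P <- matrix(c(0.5, 0.5, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE,
              dimnames = list(states, states))
  m <- markov_model(states, function(age, params) P,
                    cost = c(a = 0, b = 0, dead = 0),
                    utility = c(a = 0, b = 0, dead = 0),
                    entry_cost = c(a = 0, b = 100, dead = 0),
                    start_age = 40L)
  tr <- run_cohort(m, age_cap = 43)
  st <- accrue_rewards(tr, m$cost, m$utility, m$entry_cost)
  # inflows to b: 0.5, 0.25, 0.125
  expect_equal(st$cost_stream, c(50, 25, 12.5))
})

test_that("present value matches closed forms", {
  expect_equal(present_value(c(258, 258), 0.035), 258 + 258 / 1.035)
  expect_equal(present_value(c(1, 2, 3), 0), 6)

  # geometric stream vs closed-form annuity
  r <- 0.035
  K <- 60
  stream <- rep(1, K)
  annuity <- (1 - (1 / (1 + r))^K) / (1 - 1 / (1 + r))
  expect_equal(present_value(stream, r), annuity, tolerance = 1e-9)

  # linearity and offset
  s <- stats::runif(10)
  expect_equal(present_value(3 * s, r), 3 * present_value(s, r))
  expect_equal(present_value(s, r, offset_years = 10),
               present_value(s, r) / (1 + r)^10)
  # non-increasing in rate for non-negative streams
  expect_lt(present_value(s, 0.05), present_value(s, 0.01))
})

test_that("trace export carries cycle, age, occupancy and accruals", {
  m <- two_state_model(0.5)
  tr <- run_cohort(m, age_cap = 42)
  df <- trace_table(tr, accrue_rewards(tr, m$cost, m$utility))
  expect_equal(names(df), c("cycle", "age", "alive", "dead", "cost", "qaly"))
  expect_equal(df$age, 40:42)
  expect_equal(df$qaly[1:2], c(0.75, 0.375))
})
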