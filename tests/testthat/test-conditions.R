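# shared base-case inputs for the condition tests
fixture_env <- local({
  env <- new.env()
  function() {
    if (is.null(env$pset)) {
      env$pset <- ahc_parameter_fixture()
      env$params <- resolve_points(env$pset)
      env$lt <- adjust_id_mortality(gompertz_life_table(), 3)
    }
    env
  }
})

test_that("null hypertension incidence keeps the cohort well at zero cost", {
  e <- fixture_env()
  p <- e$params
  p[grep("^hypertension\\.incidence\\.", names(p))] <- 0
  for (arm in c("ahc", "standard")) {
    m <- build_state_model("hypertension", arm, p, e$lt)
    tr <- run_cohort(m, age_cap = 100)
    expect_true(all(tr$occupancy[, setdiff(m$states, c("well", "dead"))] == 0))
    st <- accrue_rewards(tr, m$cost, m$utility, m$entry_cost)
    expect_equal(sum(st$cost_stream), 0)
  }
})

test_that("managed hypertension carries the published relative risks", {
  e <- fixture_env()
  m <- build_state_model("hypertension", "ahc", e$params, e$lt)
  P <- m$transition_rule(45, e$params)
  q <- e$lt$qx[match(45, e$lt$ages)]
  # death under management = background mortality x RR (midpoint 0.86)
  expect_equal(P["ht_managed", "dead"], q * 0.86, tolerance = 1e-12)
  expect_equal(P["ht_unmanaged", "dead"], q)
  # stroke risk: baseline x hypertension RR, then managed RR on top
  s_un <- P["ht_unmanaged", "stroke_y1"] / (1 - q)
  s_m <- P["ht_managed", "stroke_y1"] / (1 - q * 0.86)
  expect_equal(s_un, 0.00555 * 4, tolerance = 1e-12)
  expect_equal(s_m / s_un, 0.63, tolerance = 1e-12)
})

test_that("glaucoma progression uses treated vs untreated probabilities", {
  e <- fixture_env()
  m <- build_state_model("glaucoma", "standard", e$params, e$lt)
  P <- m$transition_rule(60, e$params)
  q <- e$lt$qx[match(60, e$lt$ages)]
  expect_equal(P["tr_severe", "vi"] / (1 - q), 0.06)
  expect_equal(P["un_severe", "vi"] / (1 - q), 0.10)
  expect_equal(P["tr_mild", "tr_moderate"] / (1 - q), 0.22)
  expect_equal(P["un_mild", "un_moderate"] / (1 - q), 0.25)
})

test_that("bowel participation shifts death risk by the published ARR", {
  e <- fixture_env()
  p <- e$params
  m_ahc <- build_state_model("bowel_screening", "ahc", p, e$lt)
  m_std <- build_state_model("bowel_screening", "standard", p, e$lt)
  d_ahc <- m_ahc$transition_rule(65, p)["well", "dead"]
  d_std <- m_std$transition_rule(65, p)["well", "dead"]
  dpart <- p[["bowel.participation.diff"]]
  expect_equal(d_std - d_ahc, dpart * 0.0101, tolerance = 1e-12)
})

test_that("diabetes strata weight by the obesity proportion", {
  e <- fixture_env()
  p <- e$params
  expect_equal(p[["diabetes.obesity_proportion"]], 0.335)
  # doubling only the overweight delta moves the result by exactly the
  # overweight share of the managed incident mass
  r0 <- incremental_condition("diabetes", p, e$lt)
  p2 <- p
  p2[["diabetes.qaly_delta.overweight"]] <-
    2 * p[["diabetes.qaly_delta.overweight"]]
  r2 <- incremental_condition("diabetes", p2, e$lt)
  ratio <- (r2$inc_qaly - r0$inc_qaly) / r0$inc_qaly
  w <- 0.335 * p[["diabetes.qaly_delta.overweight"]]
  tot <- w + 0.665 * p[["diabetes.qaly_delta.non_overweight"]]
  expect_equal(ratio, w / tot, tolerance = 1e-9)
})

test_that("hearing one-cycle cascade equals brute-force enumeration", {
  e <- fixture_env()
  p <- e$params
  # immortal one-cycle cohort: survival 1 throughout the single cycle
  lt1 <- life_table(40:41, c(0, 1))
  r <- evaluate_cascade_condition("hearing", p, lt1, discount_rate = 0,
                                  age_cap = 41)
  enum_arm <- function(ref) {
    prob <- p[["hearing.problem_annual"]]
    wax <- p[["hearing.wax_share"]]
    att <- p[["hearing.attend_specialist"]]
    need <- p[["hearing.aid_required"]]
    acc <- p[["hearing.aid_accepted"]]
    # enumerate the branch tree: wax branch, specialist branch
    adopt <- prob * ref * (1 - wax) * att * need * acc
    qaly <- prob * ref * wax * p[["hearing.utility_gain.wax"]] +
      adopt / 2 * p[["hearing.utility_gain.aid"]]
    cost <- prob * ref * wax * p[["hearing.cost.wax_removal"]] +
      prob * ref * (1 - wax) * att * p[["hearing.cost.specialist_assessment"]] +
      prob * ref * (1 - wax) * att * need * p[["hearing.cost.aid_assessment"]] +
      adopt * p[["hearing.cost.aid_initial"]] +
      adopt / 2 * p[["hearing.cost.aid_followon_annual"]]
    c(cost = cost, qaly = qaly)
  }
  ahc <- enum_arm(p[["hearing.referral.ahc"]])
  std <- enum_arm(p[["hearing.referral.standard"]])
  expect_equal(r$pv_cost[["ahc"]], ahc[["cost"]], tolerance = 1e-12)
  expect_equal(r$pv_qaly[["ahc"]], ahc[["qaly"]], tolerance = 1e-12)
  expect_equal(r$inc_cost, ahc[["cost"]] - std[["cost"]], tolerance = 1e-12)
  expect_equal(r$inc_qaly, ahc[["qaly"]] - std[["qaly"]], tolerance = 1e-12)
})

test_that("equal arms give exactly zero increments for every condition", {
  e <- fixture_env()
  null_p <- resolve_points(null_effect_parameters(e$pset))
  for (cond in ahc_conditions()) {
    r <- incremental_condition(cond, null_p, e$lt)
    expect_identical(r$inc_cost, 0, info = cond)
    expect_identical(r$inc_qaly, 0, info = cond)
  }
})

test_that("raising health-check referral never lowers the QALY gain", {
  e <- fixture_env()
  for (cond in c("glaucoma", "hearing", "cataract")) {
    key <- paste0(sub("_screening", "", cond), ".referral.ahc")
    base <- incremental_condition(cond, e$params, e$lt)$inc_qaly
    for (v in c(0.92, 0.95, 1)) {
      p2 <- e$params
      p2[[key]] <- v
      expect_gte(incremental_condition(cond, p2, e$lt)$inc_qaly, base)
      base <- incremental_condition(cond, p2, e$lt)$inc_qaly
    }
  }
})

test_that("cascade branch probabilities stay in [0,1] for any draw", {
  pset <- ahc_parameter_fixture()
  dists <- param_distributions(pset)
  branch <- names(which(vapply(pset$entries, function(e) {
    e$category %in% c("probability", "proportion")
  }, logical(1))))
  set.seed(13)
  for (i in 1:200) {
    p <- sample_parameters(dists)
    expect_true(all(p[branch] >= 0 & p[branch] <= 1))
    expect_true(all(1 - p[branch] >= 0))
  }
})

test_that("condition results are isolated from other conditions' inputs", {
  e <- fixture_env()
  base <- incremental_condition("glaucoma", e$params, e$lt)
  p2 <- e$params
  p2[grep("^(hypertension|bowel|breast|diabetes|cataract|hearing|osteoporosis)\\.",
          names(p2))] <- 0.123
  mod <- incremental_condition("glaucoma", p2, e$lt)
  expect_identical(base$inc_cost, mod$inc_cost)
  expect_identical(base$inc_qaly, mod$inc_qaly)
})

test_that("state-model increments match a micro-simulation with one draw", {
  e <- fixture_env()
  p <- e$params
  set.seed(77)
  n <- 200000
  for (arm in c("ahc", "standard")) {
    m <- build_state_model("hypertension", arm, p, e$lt)
    tr <- run_cohort(m, p, 100)
    sim <- simulate_cohort_counts(m, 100, n, p)
    se <- occ_se(tr$occupancy, n)
    # joint bound over ~500 cycle-state comparisons per arm: 4 marginal SEs
    # plus a Poisson-tail allowance for states with expected counts near 0
    expect_true(all(abs(sim - tr$occupancy) <= 4 * se + 25 / n), info = arm)
  }
})

test_that("breast results scale with the female proportion", {
  e <- fixture_env()
  base <- incremental_condition("breast_screening", e$params, e$lt)
  p2 <- e$params
  p2[["breast.female_proportion"]] <- 1
  full <- incremental_condition("breast_screening", p2, e$lt)
  expect_equal(full$inc_cost, base$inc_cost / 0.5, tolerance = 1e-12)
  expect_equal(full$inc_qaly, base$inc_qaly / 0.5, tolerance = 1e-12)
})
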