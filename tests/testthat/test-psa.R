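test_that("degenerate distributions reproduce the base case with zero spread", {
  pset <- ahc_parameter_fixture()
  psa <- run_psa(pset, n_draws = 5, seed = 4, interpretation = "point")
  bc <- run_base_case(pset)
  expect_equal(psa$summary$sd_inc_cost, 0)
  expect_equal(psa$summary$sd_inc_qaly, 0)
  expect_equal(psa$summary$mean_inc_cost, bc$strategy$inc_cost_total)
  expect_equal(psa$summary$mean_inc_qaly, bc$strategy$inc_qaly_total)
})

test_that("the same seed reproduces a PSA bit-identically", {
  pset <- ahc_parameter_fixture()
  a <- run_psa(pset, n_draws = 25, seed = 42)
  b <- run_psa(pset, n_draws = 25, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$summary, b$summary)
  c <- run_psa(pset, n_draws = 25, seed = 43)
  expect_false(identical(a$draws$inc_cost, c$draws$inc_cost))
})

test_that("excluded and finite ICER draws partition the draw set", {
  pset <- ahc_parameter_fixture()
  psa <- run_psa(pset, n_draws = 60, seed = 12)
  expect_equal(psa$summary$icer_excluded + sum(is.finite(psa$draws$icer)),
               psa$n_draws)
  expect_true(all(psa$draws$flag %in%
                    c("ok", "dominant", "dominated", "undefined")))
})

test_that("ce_plane returns one row per draw in draw order", {
  pset <- ahc_parameter_fixture()
  psa <- run_psa(pset, n_draws = 10, seed = 2)
  cp <- ce_plane(psa)
  expect_equal(nrow(cp), 10)
  expect_equal(names(cp), c("inc_qaly", "inc_cost"))
  expect_equal(cp$inc_cost, psa$draws$inc_cost)
  psa$draws <- psa$draws[0, ]
  expect_error(ce_plane(psa), "empty")
})

test_that("one-way SA at the base value reproduces the plain PSA", {
  pset <- ahc_parameter_fixture()
  base_cost <- intervention_yearly_cost(intervention_components(pset))
  psa <- run_psa(pset, n_draws = 30, seed = 6)
  row <- one_way_sa(pset, parameter_name = "intervention.yearly_cost",
                    values = base_cost, n_draws = 30, seed = 6)
  expect_equal(row$mean_inc_cost, psa$summary$mean_inc_cost)
  expect_equal(row$mean_inc_qaly, psa$summary$mean_inc_qaly)
  expect_equal(row$mean_icer, psa$summary$mean_icer)
})

test_that("intervention-cost rows differ by exactly the annuity factor", {
  pset <- ahc_parameter_fixture()
  tab <- one_way_sa(pset, parameter_name = "intervention.yearly_cost",
                    values = c(50, 100), n_draws = 30, seed = 9)
  lt <- adjust_id_mortality(default_life_table(), 3)
  annuity <- intervention_cost_pv(1, survival_curve(lt, 40, 100), 0.035)
  expect_equal(tab$mean_inc_cost[2] - tab$mean_inc_cost[1], 50 * annuity,
               tolerance = 1e-6)
  expect_equal(tab$mean_inc_qaly[1], tab$mean_inc_qaly[2], tolerance = 1e-12)
})

test_that("unknown one-way parameters fail naming the parameter", {
  pset <- ahc_parameter_fixture()
  expect_error(one_way_sa(pset, parameter_name = "no.such.param",
                          values = 1, n_draws = 2, seed = 1),
               "no.such.param")
  expect_error(one_way_sa(pset, parameter_name = "bowel.positive",
                          values = numeric(0), n_draws = 2, seed = 1),
               "non-empty")
})

test_that("overriding a sampled parameter keeps common random numbers", {
  pset <- ahc_parameter_fixture()
  a <- run_psa(pset, n_draws = 20, seed = 15,
               param_overrides = c(bowel.positive = 0.02))
  b <- run_psa(pset, n_draws = 20, seed = 15,
               param_overrides = c(bowel.positive = 0.021))
  # only the bowel cascade responds; QALY paths stay identical
  expect_equal(a$draws$inc_qaly, b$draws$inc_qaly, tolerance = 1e-12)
  expect_true(all(b$draws$inc_cost > a$draws$inc_cost))
})

test_that("PSA mean converges on the deterministic base case", {
  pset <- ahc_parameter_fixture()
  psa <- run_psa(pset, n_draws = 800, seed = 21)
  bc <- run_base_case(pset)
  se <- psa$summary$sd_inc_qaly / sqrt(psa$n_draws)
  # distributions are mean-matched to the base points; residual gap is
  # model nonlinearity, which must stay within Monte Carlo resolution
  expect_lt(abs(psa$summary$mean_inc_qaly - bc$strategy$inc_qaly_total),
            max(4 * se, 0.1 * bc$strategy$inc_qaly_total))
})

test_that("mean per-draw ICER exceeds the ratio of means on the fixture", {
  pset <- ahc_parameter_fixture()
  psa <- run_psa(pset, n_draws = 300, seed = 18)
  # positively-skewed QALY denominators push the ratio mean up (Jensen)
  expect_gt(psa$summary$mean_icer, psa$summary$icer_ratio_of_means)
})
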