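#' Conditions covered by the annual-health-check model
#'
#' Eight ageing-relevant conditions are modelled, each as either a
#' state-transition Markov model (hypertension, glaucoma, osteoporosis,
#' bowel and breast screening) or a probability cascade over the
#' survival-weighted incident population (diabetes, cataract, hearing).
#' Coronary heart disease and stroke enter only inside the hypertension
#' model, and hip fracture only inside the osteoporosis model, to avoid
#' double counting.
#'
#' @return character vector of condition tags.
#' @export
ahc_conditions <- function() {
  c("hypertension", "glaucoma", "osteoporosis", "bowel_screening",
    "breast_screening", "diabetes", "cataract", "hearing")
}

state_model_conditions <- function() {
  c("hypertension", "glaucoma", "osteoporosis", "bowel_screening",
    "breast_screening")
}

cascade_conditions <- function() c("diabetes", "cataract", "hearing")

#' Cohort starting age for a condition model
#'
#' Screening models start at the age the national programme begins (bowel
#' 60, breast 50); osteoporosis starts at 50 where incidence rises steeply;
#' everything else starts at the common base age 40.
#'
#' @param condition a condition tag.
#' @return integer starting age.
#' @export
condition_start_age <- function(condition) {
  switch(condition,
    osteoporosis = 50L, breast_screening = 50L, bowel_screening = 60L,
    hypertension = , glaucoma = , diabetes = , cataract = , hearing = 40L,
    stop_ahc("unknown condition '%s'", condition))
}

#' Parameter names a condition model resolves
#'
#' Used by the load-time completeness check and by the fixture
#' cross-reference test: every name returned here must exist in any full
#' parameter set.
#'
#' @param condition a condition tag.
#' @return character vector of parameter names.
#' @export
required_parameters <- function(condition) {
  switch(condition,
    hypertension = c(
      paste0("hypertension.incidence.", c("40_49", "50_64", "65_plus")),
      paste0("hypertension.baseline_stroke.", c("40_49", "50_64", "65_plus")),
      paste0("hypertension.baseline_chd.", c("40_49", "50_64", "65_plus")),
      "hypertension.rr_stroke", "hypertension.rr_chd",
      "hypertension.managed.ahc", "hypertension.managed.standard",
      "hypertension.adherence",
      paste0("hypertension.rr_stroke_managed.", c("40_59", "60_plus")),
      paste0("hypertension.rr_chd_managed.", c("40_59", "60_plus")),
      paste0("hypertension.rr_death_managed.", c("40_59", "60_plus")),
      "hypertension.cost.diagnosis", "hypertension.cost.management_annual",
      "hypertension.cost.stroke_first_year", "hypertension.cost.stroke_subsequent",
      "hypertension.cost.chd_first_year", "hypertension.cost.chd_subsequent",
      "hypertension.utility.no_event", "hypertension.utility.stroke",
      "hypertension.utility.chd"),
    glaucoma = c(
      paste0("glaucoma.incidence.", c("40_49", "50_64", "65_plus")),
      "glaucoma.referral.ahc", "glaucoma.referral.standard",
      "glaucoma.adherence",
      paste0("glaucoma.progression.",
             rep(c("mild_to_moderate", "moderate_to_severe", "severe_to_vi"),
                 each = 2), ".", c("treated", "untreated")),
      "glaucoma.cost.initial_test", "glaucoma.cost.diagnosis_test",
      "glaucoma.cost.mild_annual", "glaucoma.cost.moderate_annual",
      "glaucoma.cost.severe_annual", "glaucoma.cost.vi_annual",
      "glaucoma.utility.mild", "glaucoma.utility.moderate",
      "glaucoma.utility.severe", "glaucoma.utility.vi"),
    osteoporosis = c(
      paste0("osteoporosis.incidence.", c("50_64", "65_plus")),
      paste0("osteoporosis.fracture.", c("50_64", "65_plus")),
      "osteoporosis.investigated.ahc", "osteoporosis.investigated.standard",
      "osteoporosis.prescription", "osteoporosis.rr_fracture_treated",
      "osteoporosis.cost.dxa", "osteoporosis.cost.medication_annual",
      "osteoporosis.cost.hip_fracture_year1", "osteoporosis.cost.hip_fracture_year2",
      "osteoporosis.utility.hip_fracture_year1",
      "osteoporosis.utility.no_fracture.50_60",
      "osteoporosis.utility.no_fracture.60_plus"),
    bowel_screening = c(
      paste0("bowel.incidence.", c("50_64", "65_plus")),
      "bowel.participation.standard", "bowel.participation.diff",
      "bowel.positive", "bowel.clinic_attendance", "bowel.cancer_if_positive",
      "bowel.polyps_if_positive", "bowel.bleeding_if_positive",
      "bowel.arr_death",
      "bowel.cost.fobt", "bowel.cost.colonoscopy", "bowel.cost.adenoma_removal",
      "bowel.cost.bleeding_admission", "bowel.cost.treatment_screen_detected",
      "bowel.cost.treatment_clinical", "bowel.utility.cancer"),
    breast_screening = c(
      paste0("breast.incidence.", c("50_64", "65_plus")),
      "breast.participation.ahc", "breast.participation.standard",
      "breast.detected_by_mammogram", "breast.rr_death_invited",
      "breast.rr_overdiagnosis", "breast.cancer_mortality_annual",
      "breast.female_proportion",
      "breast.cost.mammogram", "breast.cost.overdiagnosis",
      "breast.cost_delta.early_vs_late.under_65",
      "breast.cost_delta.early_vs_late.65_plus",
      "breast.utility.cancer"),
    diabetes = c(
      paste0("diabetes.incidence.", c("40_49", "50_64", "65_plus")),
      "diabetes.overlap_adjustment", "diabetes.managed.ahc",
      "diabetes.managed.standard", "diabetes.obesity_proportion",
      "diabetes.cost_delta.overweight", "diabetes.cost_delta.non_overweight",
      "diabetes.qaly_delta.overweight", "diabetes.qaly_delta.non_overweight"),
    cataract = c(
      paste0("cataract.incidence.", c("40_49", "50_64", "65_plus")),
      "cataract.referral.ahc", "cataract.referral.standard",
      "cataract.glasses_if_referred", "cataract.surgery_if_referred",
      "cataract.cost.initial_test", "cataract.cost.diagnosis_test",
      "cataract.cost.surgery_lifetime", "cataract.qaly_gain.surgery"),
    hearing = c(
      "hearing.problem_annual", "hearing.referral.ahc",
      "hearing.referral.standard", "hearing.wax_share",
      "hearing.attend_specialist", "hearing.aid_required",
      "hearing.aid_accepted",
      "hearing.cost.wax_removal", "hearing.cost.specialist_assessment",
      "hearing.cost.aid_assessment", "hearing.cost.aid_initial",
      "hearing.cost.aid_followon_annual",
      "hearing.utility_gain.wax", "hearing.utility_gain.aid"),
    stop_ahc("unknown condition '%s'", condition))
}

# value of an age-banded parameter family; bands = named upper bounds
age_band_value <- function(params, prefix, age, bands) {
  lab <- names(bands)[which(age <= bands)[1]]
  pget(params, paste(prefix, lab, sep = "."))
}

condition_result <- function(condition, pv_cost, pv_qaly) {
  structure(
    list(condition = condition,
         pv_cost = pv_cost, pv_qaly = pv_qaly,
         inc_cost = unname(pv_cost[["ahc"]] - pv_cost[["standard"]]),
         inc_qaly = unname(pv_qaly[["ahc"]] - pv_qaly[["standard"]])),
    class = "ahc_condition_result"
  )
}

#' @export
print.ahc_condition_result <- function(x, ...) {
  cat(sprintf("<%s: inc cost %.2f GBP, inc QALY %.5f per person>\n",
              x$condition, x$inc_cost, x$inc_qaly))
  invisible(x)
}

#' Incremental result of one condition model
#'
#' Evaluates the condition under both strategy arms with the same parameter
#' draw (a common-random-numbers contract: arm differences reflect only the
#' arm-specific parameters) and returns the per-arm present values and
#' their differences, discounted to the common base age 40.
#'
#' @param condition a condition tag.
#' @param params named parameter map (one draw or the resolved base case).
#' @param lt an ID-mortality-adjusted [life_table()].
#' @param discount_rate annual discount rate.
#' @param age_cap terminal age.
#' @return an `ahc_condition_result`.
#' @export
incremental_condition <- function(condition, params, lt,
                                  discount_rate = 0.035, age_cap = 100) {
  if (condition %in% cascade_conditions()) {
    return(evaluate_cascade_condition(condition, params, lt,
                                      discount_rate, age_cap))
  }
  if (!condition %in% state_model_conditions()) {
    stop_ahc("unknown condition '%s'", condition)
  }
  start <- condition_start_age(condition)
  offset <- start - 40
  one_arm <- function(arm) {
    model <- build_state_model(condition, arm, params, lt)
    trace <- run_cohort(model, params, age_cap)
    st <- accrue_rewards(trace, model$cost, model$utility, model$entry_cost)
    c(cost = present_value(st$cost_stream, discount_rate, offset),
      qaly = present_value(st$qaly_stream, discount_rate, offset))
  }
  ahc <- one_arm("ahc")
  std <- one_arm("standard")
  scale <- if (condition == "breast_screening") {
    pget(params, "breast.female_proportion")
  } else 1
  condition_result(condition,
                   pv_cost = c(ahc = scale * ahc[["cost"]],
                               standard = scale * std[["cost"]]),
                   pv_qaly = c(ahc = scale * ahc[["qaly"]],
                               standard = scale * std[["qaly"]]))
}

#' Evaluate every condition model for one parameter draw
#'
#' @inheritParams incremental_condition
#' @param conditions condition tags to evaluate.
#' @return named list of `ahc_condition_result` objects.
#' @export
evaluate_all_conditions <- function(params, lt, discount_rate = 0.035,
                                    age_cap = 100,
                                    conditions = ahc_conditions()) {
  res <- lapply(conditions, incremental_condition, params = params, lt = lt,
                discount_rate = discount_rate, age_cap = age_cap)
  stats::setNames(res, conditions)
}

#' Force both strategy arms to identical effectiveness
#'
#' Sets every arm-differentiating parameter of the annual-health-check arm
#' equal to its standard-care counterpart (and the bowel participation
#' difference to zero). With the result, every condition's incremental cost
#' and QALY are exactly zero — the null-effect identity used to verify that
#' arm differences flow only through these parameters.
#'
#' @param pset an `ahc_parameter_set`.
#' @return the modified parameter set.
#' @export
null_effect_parameters <- function(pset) {
  pairs <- c("hypertension.managed", "glaucoma.referral", "cataract.referral",
             "hearing.referral", "osteoporosis.investigated",
             "breast.participation", "diabetes.managed")
  for (p in pairs) {
    std <- pset$entries[[paste0(p, ".standard")]]
    ahc <- pset$entries[[paste0(p, ".ahc")]]
    for (f in c("low", "high", "point", "sd")) ahc[[f]] <- std[[f]]
    pset$entries[[paste0(p, ".ahc")]] <- ahc
  }
  d <- pset$entries[["bowel.participation.diff"]]
  d$low <- d$high <- 0
  d$point <- 0
  d$sd <- NULL
  pset$entries[["bowel.participation.diff"]] <- d
  pset
}
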