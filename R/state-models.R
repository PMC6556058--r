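#' Build the Markov model for one condition and strategy arm
#'
#' Constructs the state space, age-dependent transition rule and per-state
#' rewards for the five state-transition conditions. The two strategy arms
#' differ only in the arm-specific effectiveness parameters (identification,
#' screening participation, investigation); all epidemiology, costs and
#' utilities are shared.
#'
#' State structures (besides `well` and `dead`):
#' \describe{
#'   \item{hypertension}{managed / unmanaged hypertension; first-year and
#'     subsequent post-stroke and post-CHD states. Management (identified
#'     and managed x 75% adherence, applied at incidence) lowers stroke,
#'     CHD and death risks via age-banded relative risks.}
#'   \item{glaucoma}{treated and untreated mild/moderate/severe disease and
#'     visual impairment; referral to an eye exam x treatment adherence
#'     decides the treated split; treatment slows stage progression.}
#'   \item{osteoporosis}{investigated-and-treated vs untreated disease from
#'     age 50; hip fracture with first-year, second-year and post states;
#'     anti-osteoporotic treatment scales fracture risk.}
#'   \item{bowel_screening}{from age 60; annual FOBT participation drives a
#'     screening cost cascade and an absolute reduction in death risk;
#'     non-participants' cancers are treated at the clinically-detected
#'     cost.}
#'   \item{breast_screening}{from age 50, females (results scaled by the
#'     female proportion); screen-participant cancers are detected early
#'     (lifetime cost offset) and carry the invited-women death relative
#'     risk; over-diagnosis costs scale with excess screen detection.}
#' }
#'
#' @param condition one of the state-model condition tags.
#' @param arm `"ahc"` or `"standard"`.
#' @param params named parameter map.
#' @param lt an ID-adjusted [life_table()].
#' @return an [markov_model()].
#' @export
build_state_model <- function(condition, arm = c("ahc", "standard"),
                              params, lt) {
  arm <- match.arg(arm)
  switch(condition,
    hypertension = model_hypertension(arm, params, lt),
    glaucoma = model_glaucoma(arm, params, lt),
    osteoporosis = model_osteoporosis(arm, params, lt),
    bowel_screening = model_bowel(arm, params, lt),
    breast_screening = model_breast(arm, params, lt),
    stop_ahc("unknown state-model condition '%s'", condition))
}

# transition-row helper: distribute survivors over competing destinations
row_fill <- function(n, states, ...) {
  r <- stats::setNames(numeric(n), states)
  dest <- list(...)
  for (nm in names(dest)) r[nm] <- dest[[nm]]
  r
}

bands3 <- c("40_49" = 49, "50_64" = 64, "65_plus" = Inf)
bands2_osteo <- c("50_64" = 64, "65_plus" = Inf)
bands_rr <- c("40_59" = 59, "60_plus" = Inf)

model_hypertension <- function(arm, params, lt) {
  g <- function(n) pget(params, paste0("hypertension.", n))
  p_split <- g(paste0("managed.", arm)) * g("adherence")
  rr_stroke <- g("rr_stroke")
  rr_chd <- g("rr_chd")
  states <- c("well", "ht_managed", "ht_unmanaged", "stroke_y1", "stroke_post",
              "chd_y1", "chd_post", "dead")
  n <- length(states)
  trans <- function(age, ...) {
    q <- qx_at(lt, age)
    inc <- age_band_value(params, "hypertension.incidence", age, bands3)
    s_un <- min(1, age_band_value(params, "hypertension.baseline_stroke",
                                  age, bands3) * rr_stroke)
    c_un <- min(1, age_band_value(params, "hypertension.baseline_chd",
                                  age, bands3) * rr_chd)
    s_m <- min(1, s_un * age_band_value(params, "hypertension.rr_stroke_managed",
                                        age, bands_rr))
    c_m <- min(1, c_un * age_band_value(params, "hypertension.rr_chd_managed",
                                        age, bands_rr))
    d_un <- q
    d_m <- min(1, q * age_band_value(params, "hypertension.rr_death_managed",
                                     age, bands_rr))
    ht_row <- function(d, s, cc, stay) {
      r <- row_fill(n, states, dead = d, stroke_y1 = (1 - d) * s,
                    chd_y1 = (1 - d) * (1 - s) * cc)
      r[stay] <- (1 - d) * (1 - s) * (1 - cc)
      r
    }
    rbind(
      well = row_fill(n, states, dead = q,
                      ht_managed = (1 - q) * inc * p_split,
                      ht_unmanaged = (1 - q) * inc * (1 - p_split),
                      well = (1 - q) * (1 - inc)),
      ht_managed = ht_row(d_m, s_m, c_m, "ht_managed"),
      ht_unmanaged = ht_row(d_un, s_un, c_un, "ht_unmanaged"),
      stroke_y1 = row_fill(n, states, dead = q, stroke_post = 1 - q),
      stroke_post = row_fill(n, states, dead = q, stroke_post = 1 - q),
      chd_y1 = row_fill(n, states, dead = q, chd_post = 1 - q),
      chd_post = row_fill(n, states, dead = q, chd_post = 1 - q),
      dead = row_fill(n, states, dead = 1)
    )
  }
  u <- g("utility.no_event")
  markov_model(
    states, trans,
    cost = c(well = 0, ht_managed = g("cost.management_annual"),
             ht_unmanaged = 0,
             stroke_y1 = g("cost.stroke_first_year"),
             stroke_post = g("cost.stroke_subsequent"),
             chd_y1 = g("cost.chd_first_year"),
             chd_post = g("cost.chd_subsequent"), dead = 0),
    utility = c(well = u, ht_managed = u, ht_unmanaged = u,
                stroke_y1 = g("utility.stroke"),
                stroke_post = g("utility.stroke"),
                chd_y1 = g("utility.chd"), chd_post = g("utility.chd"),
                dead = 0),
    entry_cost = c(well = 0, ht_managed = g("cost.diagnosis"),
                   ht_unmanaged = 0, stroke_y1 = 0, stroke_post = 0,
                   chd_y1 = 0, chd_post = 0, dead = 0),
    start_age = 40L
  )
}

model_glaucoma <- function(arm, params, lt) {
  g <- function(n) pget(params, paste0("glaucoma.", n))
  referral <- g(paste0("referral.", arm))
  adherence <- g("adherence")
  p_tr <- referral * adherence
  # referred-but-non-adherent share among the untreated entrants: they
  # still incur the eye-exam work-up costs
  nonadh_share <- if (p_tr < 1) referral * (1 - adherence) / (1 - p_tr) else 0
  tests <- g("cost.initial_test") + g("cost.diagnosis_test")
  pr <- function(stage, tr) {
    g(paste0("progression.", stage, if (tr) ".treated" else ".untreated"))
  }
  states <- c("well", "tr_mild", "tr_moderate", "tr_severe",
              "un_mild", "un_moderate", "un_severe", "vi", "dead")
  n <- length(states)
  stage_row <- function(q, here, nxt, p) {
    r <- row_fill(n, states, dead = q)
    r[nxt] <- (1 - q) * p
    r[here] <- (1 - q) * (1 - p)
    r
  }
  trans <- function(age, ...) {
    q <- qx_at(lt, age)
    inc <- age_band_value(params, "glaucoma.incidence", age, bands3)
    rbind(
      well = row_fill(n, states, dead = q,
                      tr_mild = (1 - q) * inc * p_tr,
                      un_mild = (1 - q) * inc * (1 - p_tr),
                      well = (1 - q) * (1 - inc)),
      tr_mild = stage_row(q, "tr_mild", "tr_moderate",
                          pr("mild_to_moderate", TRUE)),
      tr_moderate = stage_row(q, "tr_moderate", "tr_severe",
                              pr("moderate_to_severe", TRUE)),
      tr_severe = stage_row(q, "tr_severe", "vi", pr("severe_to_vi", TRUE)),
      un_mild = stage_row(q, "un_mild", "un_moderate",
                          pr("mild_to_moderate", FALSE)),
      un_moderate = stage_row(q, "un_moderate", "un_severe",
                              pr("moderate_to_severe", FALSE)),
      un_severe = stage_row(q, "un_severe", "vi", pr("severe_to_vi", FALSE)),
      vi = row_fill(n, states, dead = q, vi = 1 - q),
      dead = row_fill(n, states, dead = 1)
    )
  }
  u_base <- pget(params, "global.utility.baseline")
  markov_model(
    states, trans,
    cost = c(well = 0, tr_mild = g("cost.mild_annual"),
             tr_moderate = g("cost.moderate_annual"),
             tr_severe = g("cost.severe_annual"),
             un_mild = 0, un_moderate = 0, un_severe = 0,
             vi = g("cost.vi_annual"), dead = 0),
    utility = c(well = u_base, tr_mild = g("utility.mild"),
                tr_moderate = g("utility.moderate"),
                tr_severe = g("utility.severe"),
                un_mild = g("utility.mild"),
                un_moderate = g("utility.moderate"),
                un_severe = g("utility.severe"),
                vi = g("utility.vi"), dead = 0),
    entry_cost = c(well = 0, tr_mild = tests, tr_moderate = 0, tr_severe = 0,
                   un_mild = tests * nonadh_share, un_moderate = 0,
                   un_severe = 0, vi = 0, dead = 0),
    start_age = 40L
  )
}

model_osteoporosis <- function(arm, params, lt) {
  g <- function(n) pget(params, paste0("osteoporosis.", n))
  p_tr <- g(paste0("investigated.", arm)) * g("prescription")
  rr_fx <- g("rr_fracture_treated")
  states <- c("well", "treated", "untreated", "hip_y1", "hip_y2",
              "hip_post", "dead")
  n <- length(states)
  trans <- function(age, ...) {
    q <- qx_at(lt, age)
    inc <- age_band_value(params, "osteoporosis.incidence", age, bands2_osteo)
    fx_un <- age_band_value(params, "osteoporosis.fracture", age, bands2_osteo)
    fx_tr <- min(1, fx_un * rr_fx)
    dis_row <- function(here, fx) {
      r <- row_fill(n, states, dead = q, hip_y1 = (1 - q) * fx)
      r[here] <- (1 - q) * (1 - fx)
      r
    }
    rbind(
      well = row_fill(n, states, dead = q,
                      treated = (1 - q) * inc * p_tr,
                      untreated = (1 - q) * inc * (1 - p_tr),
                      well = (1 - q) * (1 - inc)),
      treated = dis_row("treated", fx_tr),
      untreated = dis_row("untreated", fx_un),
      hip_y1 = row_fill(n, states, dead = q, hip_y2 = 1 - q),
      hip_y2 = row_fill(n, states, dead = q, hip_post = 1 - q),
      hip_post = row_fill(n, states, dead = q, hip_post = 1 - q),
      dead = row_fill(n, states, dead = 1)
    )
  }
  u_nofx <- function(age) {
    age_band_value(params, "osteoporosis.utility.no_fracture", age,
                   c("50_60" = 60, "60_plus" = Inf))
  }
  markov_model(
    states, trans,
    cost = c(well = 0, treated = g("cost.medication_annual"), untreated = 0,
             hip_y1 = g("cost.hip_fracture_year1"),
             hip_y2 = g("cost.hip_fracture_year2"), hip_post = 0, dead = 0),
    utility = function(age) {
      u <- u_nofx(age)
      c(well = u, treated = u, untreated = u,
        hip_y1 = g("utility.hip_fracture_year1"),
        hip_y2 = u, hip_post = u, dead = 0)
    },
    entry_cost = c(well = 0, treated = g("cost.dxa"), untreated = 0,
                   hip_y1 = 0, hip_y2 = 0, hip_post = 0, dead = 0),
    start_age = 50L
  )
}

model_bowel <- function(arm, params, lt) {
  g <- function(n) pget(params, paste0("bowel.", n))
  part <- g("participation.standard")
  if (arm == "ahc") part <- min(1, part + g("participation.diff"))
  arr <- g("arr_death")
  # expected screening-cascade cost per participating, cancer-free person
  # and cycle: FOBT kits, then work-up of positives
  cascade_cost <- g("cost.fobt") + g("positive") * g("clinic_attendance") *
    (g("cost.colonoscopy") +
     g("cancer_if_positive") * g("cost.treatment_screen_detected") +
     g("polyps_if_positive") * g("cost.adenoma_removal") +
     g("bleeding_if_positive") * g("cost.bleeding_admission"))
  states <- c("well", "cancer", "dead")
  n <- length(states)
  trans <- function(age, ...) {
    q <- qx_at(lt, age)
    qd <- min(1, max(0, q - part * arr))
    inc <- age_band_value(params, "bowel.incidence", age, bands2_osteo)
    rbind(
      well = row_fill(n, states, dead = qd, cancer = (1 - qd) * inc,
                      well = (1 - qd) * (1 - inc)),
      cancer = row_fill(n, states, dead = q, cancer = 1 - q),
      dead = row_fill(n, states, dead = 1)
    )
  }
  markov_model(
    states, trans,
    cost = c(well = part * cascade_cost, cancer = 0, dead = 0),
    utility = c(well = pget(params, "global.utility.baseline"),
                cancer = g("utility.cancer"), dead = 0),
    entry_cost = c(well = 0,
                   cancer = (1 - part) * g("cost.treatment_clinical"),
                   dead = 0),
    start_age = 60L
  )
}

model_breast <- function(arm, params, lt) {
  g <- function(n) pget(params, paste0("breast.", n))
  part <- g(paste0("participation.", arm))
  p_detect <- g("detected_by_mammogram")
  rr_death <- g("rr_death_invited")
  excess <- g("cancer_mortality_annual")
  rr_od <- g("rr_overdiagnosis")
  states <- c("well", "cancer_screened", "cancer_unscreened", "dead")
  n <- length(states)
  inc_at <- function(age) {
    age_band_value(params, "breast.incidence", age,
                   c("50_64" = 64, "65_plus" = Inf))
  }
  trans <- function(age, ...) {
    q <- qx_at(lt, age)
    inc <- inc_at(age)
    rbind(
      well = row_fill(n, states, dead = q,
                      cancer_screened = (1 - q) * inc * part,
                      cancer_unscreened = (1 - q) * inc * (1 - part),
                      well = (1 - q) * (1 - inc)),
      cancer_screened = row_fill(n, states,
                                 dead = min(1, q + excess * rr_death),
                                 cancer_screened =
                                   1 - min(1, q + excess * rr_death)),
      cancer_unscreened = row_fill(n, states, dead = min(1, q + excess),
                                   cancer_unscreened =
                                     1 - min(1, q + excess)),
      dead = row_fill(n, states, dead = 1)
    )
  }
  delta_at <- function(age) {
    age_band_value(params, "breast.cost_delta.early_vs_late", age,
                   c("under_65" = 64, "65_plus" = Inf))
  }
  u_base <- pget(params, "global.utility.baseline")
  u_ca <- g("utility.cancer")
  markov_model(
    states, trans,
    # mammogram cost per participant plus treatment of over-diagnosed
    # screen-detected cancers (excess detection scales with rr_od - 1)
    cost = function(age) {
      c(well = part * g("cost.mammogram") +
          part * inc_at(age) * max(0, rr_od - 1) * g("cost.overdiagnosis"),
        cancer_screened = 0, cancer_unscreened = 0, dead = 0)
    },
    utility = c(well = u_base, cancer_screened = u_ca,
                cancer_unscreened = u_ca, dead = 0),
    # early detection assigns the printed lifetime cost difference
    entry_cost = function(age) {
      c(well = 0, cancer_screened = p_detect * delta_at(age),
        cancer_unscreened = 0, dead = 0)
    },
    start_age = 50L
  )
}
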