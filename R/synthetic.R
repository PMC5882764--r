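#' Configuration for the synthetic lung-cancer cohort generator
#'
#' Defaults emulate a 118-patient ambulatory lung-cancer cohort: marginal
#' prevalences of every covariate, a categorical TNM stage distribution
#' (advanced disease is derived from stage, never drawn), log-normal
#' pre-chemotherapy blood counts whose threshold-crossing probabilities
#' match the configured prevalences, and a logistic VTE outcome driven by
#' three active factors — a high COMPASS-CAT score (computed from each
#' patient's own generated covariates), gemcitabine-based chemotherapy and
#' atrial fibrillation — with odds ratios 8.73, 3.37 and 7.19 and an
#' intercept calibrated so the expected VTE rate is 16.9%.
#'
#' Covariates are drawn independently apart from the built-in couplings
#' (stage -> advanced disease, obesity == bmi_ge_35, blood counts -> their
#' threshold indicators); real comorbidities are correlated, so synthetic
#' joint frequencies should not be over-interpreted.
#'
#' @param n cohort size (default 118).
#' @param seed integer seed governing every draw.
#' @param prevalences named numeric vector of marginal probabilities;
#'   entries replace the defaults (see `synthetic_defaults()`).
#' @param effect_ors named odds ratios of the active outcome factors
#'   (default `c(high_compass_cat = 8.73, gemcitabine_chemo = 3.37,
#'   atrial_fibrillation = 7.19)`).
#' @param target_vte_rate expected event probability (default 0.169).
#' @param months_max upper bound of the uniform time-since-diagnosis draw,
#'   months (default 12; about half the patients then fire the <= 6-month
#'   COMPASS-CAT item).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 118L, seed = 1L, prevalences = NULL,
                             effect_ors = NULL, target_vte_rate = 0.169,
                             months_max = 12) {
  prev <- synthetic_defaults()
  if (!is.null(prevalences)) {
    unknown <- setdiff(names(prevalences), names(prev))
    if (length(unknown)) {
      stopf("synthetic_config: unknown prevalence name(s): %s",
            paste(unknown, collapse = ", "))
    }
    prev[names(prevalences)] <- prevalences
  }
  ors <- c(high_compass_cat = 8.73, gemcitabine_chemo = 3.37,
           atrial_fibrillation = 7.19)
  if (!is.null(effect_ors)) {
    unknown <- setdiff(names(effect_ors), names(ors))
    if (length(unknown)) {
      stopf("synthetic_config: unknown effect name(s): %s",
            paste(unknown, collapse = ", "))
    }
    ors[names(effect_ors)] <- effect_ors
  }
  stopifnot(n >= 0, all(prev >= 0 & prev <= 1), all(ors > 0),
            target_vte_rate > 0, target_vte_rate < 1, months_max > 0)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalences = prev, effect_ors = ors,
                 target_vte_rate = target_vte_rate,
                 months_max = months_max,
                 stage_probs = stage_distribution(),
                 histology_probs = histology_distribution()),
            class = "synthetic_config")
}

# Marginal prevalences of the emulated cohort (fractions of 118 patients).
synthetic_defaults <- function() {
  c(male = 0.58,
    who_ps_ge2 = 0.15,
    bmi_ge_35 = 6 / 118,
    coronary_artery_disease = 0.27,
    heart_failure = 5 / 118,
    hyperlipidemia = 0.46,
    hypertension = 0.60,
    atrial_fibrillation = 0.11,
    stroke = 2 / 118,
    peripheral_artery_disease = 0.03,
    diabetes = 0.20,
    copd = 0.21,
    asthma = 6 / 118,
    chronic_kidney_disease = 0.13,
    history_other_malignancy = 0.20,
    personal_vte_history = 5 / 118,
    recent_hospitalization = 0.56,
    platinum_chemo = 0.81,
    gemcitabine_chemo = 0.21,
    anthracycline_chemo = 0,
    central_venous_catheter = 7 / 118,
    esa_use = 0,
    platelets_gt_350 = 0.34,
    leukocytes_gt_11 = 0.20,
    hemoglobin_lt_10 = 4 / 118,
    death = 0.64)
}

# TNM stage counts of the emulated 118-patient cohort.
stage_distribution <- function() {
  c(IA = 1, IB = 4, IIA = 4, IIB = 6, IIIA = 16, IIIB = 15, IV = 72) / 118
}

histology_distribution <- function() {
  c(squamous = 37, adenocarcinoma = 57, small_cell = 21,
    adenoid_cystic = 1, nos = 2) / 118
}

# Log-normal blood-count draws. sdlog values are fixed at realistic
# coefficients of variation; meanlog is solved so the threshold-crossing
# probability equals the configured prevalence:
#   P(X > thr) = p  =>  meanlog = log(thr) - sdlog * qnorm(1 - p).
blood_count_params <- function(prev) {
  list(
    platelets = list(sdlog = 0.35,
      meanlog = log(350) - 0.35 * stats::qnorm(1 - prev[["platelets_gt_350"]])),
    leukocytes = list(sdlog = 0.40,
      meanlog = log(11) - 0.40 * stats::qnorm(1 - prev[["leukocytes_gt_11"]])),
    hemoglobin = list(sdlog = 0.12,
      meanlog = log(10) - 0.12 * stats::qnorm(prev[["hemoglobin_lt_10"]]))
  )
}

# Draw the covariate part of a cohort (no outcome). Field draw order is
# fixed and part of the reproducibility contract: sex, age, histology,
# stage, who_ps, bmi/obesity, the comorbidity flags in schema order,
# history/hospitalization flags, chemo flags, catheter, months since
# diagnosis, then the three blood counts.
draw_covariates <- function(n, config) {
  prev <- config$prevalences
  flag <- function(p) stats::runif(n) < p
  sex <- ifelse(flag(prev[["male"]]), "male", "female")
  age <- pmax(39L, pmin(83L, as.integer(round(stats::rnorm(n, 64, 9)))))
  histology <- sample(names(config$histology_probs), n, replace = TRUE,
                      prob = config$histology_probs)
  tnm_stage <- sample(names(config$stage_probs), n, replace = TRUE,
                      prob = config$stage_probs)
  ps_hi <- flag(prev[["who_ps_ge2"]])
  who_ps <- ifelse(ps_hi,
                   sample(2:4, n, replace = TRUE, prob = c(0.80, 0.15, 0.05)),
                   sample(0:1, n, replace = TRUE))
  bmi <- flag(prev[["bmi_ge_35"]])
  bc <- blood_count_params(prev)
  df <- data.frame(
    patient_id = sprintf("SYN%05d", seq_len(max(n, 0L))),
    age = age, sex = sex, histology = histology, tnm_stage = tnm_stage,
    who_ps = as.integer(who_ps),
    bmi_ge_35 = bmi,
    coronary_artery_disease = flag(prev[["coronary_artery_disease"]]),
    heart_failure = flag(prev[["heart_failure"]]),
    hyperlipidemia = flag(prev[["hyperlipidemia"]]),
    hypertension = flag(prev[["hypertension"]]),
    atrial_fibrillation = flag(prev[["atrial_fibrillation"]]),
    stroke = flag(prev[["stroke"]]),
    peripheral_artery_disease = flag(prev[["peripheral_artery_disease"]]),
    diabetes = flag(prev[["diabetes"]]),
    copd = flag(prev[["copd"]]),
    asthma = flag(prev[["asthma"]]),
    chronic_kidney_disease = flag(prev[["chronic_kidney_disease"]]),
    obesity = bmi,  # same BMI >= 35 definition, coupled by construction
    history_other_malignancy = flag(prev[["history_other_malignancy"]]),
    personal_vte_history = flag(prev[["personal_vte_history"]]),
    recent_hospitalization = flag(prev[["recent_hospitalization"]]),
    platinum_chemo = flag(prev[["platinum_chemo"]]),
    gemcitabine_chemo = flag(prev[["gemcitabine_chemo"]]),
    anthracycline_chemo = flag(prev[["anthracycline_chemo"]]),
    central_venous_catheter = flag(prev[["central_venous_catheter"]]),
    months_since_diagnosis = stats::runif(n, 0, config$months_max),
    esa_use = flag(prev[["esa_use"]]),
    platelets = stats::rlnorm(n, bc$platelets$meanlog, bc$platelets$sdlog),
    leukocytes = stats::rlnorm(n, bc$leukocytes$meanlog, bc$leukocytes$sdlog),
    hemoglobin = stats::rlnorm(n, bc$hemoglobin$meanlog, bc$hemoglobin$sdlog),
    stringsAsFactors = FALSE)
  df[seq_len(n), , drop = FALSE]
}

# Linear-predictor offsets (sum of log-OR terms) for the active factors.
active_factor_eta <- function(df, effect_ors) {
  log(effect_ors[["high_compass_cat"]]) * (compass_points_vec(df) >= 7) +
    log(effect_ors[["gemcitabine_chemo"]]) * df$gemcitabine_chemo +
    log(effect_ors[["atrial_fibrillation"]]) * df$atrial_fibrillation
}

#' Calibrate the outcome-model intercept
#'
#' Finds the intercept `b0` of the logistic VTE model such that the
#' expected event rate over the covariate distribution equals
#' `target_vte_rate` to within 1e-4, by bisection over a Monte-Carlo
#' covariate sample drawn with a fixed internal seed (so the calibration
#' is a deterministic function of the configuration, independent of the
#' cohort seed). With all effect odds ratios at 1 the closed form
#' `qlogis(target)` is recovered.
#'
#' @param config a [synthetic_config()].
#' @param mc_n Monte-Carlo sample size (default 40000).
#' @return the calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config, mc_n = 40000L) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(190418L)  # fixed internal calibration seed
  cov <- draw_covariates(mc_n, config)
  eta <- active_factor_eta(cov, config$effect_ors)
  rate <- function(b0) mean(stats::plogis(b0 + eta))
  lo <- -30; hi <- 30
  if (config$target_vte_rate <= rate(lo) || config$target_vte_rate >= rate(hi)) {
    stopf("calibrate_intercept: target rate %.4g outside achievable range (%.4g, %.4g)",
          config$target_vte_rate, rate(lo), rate(hi))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (rate(mid) < config$target_vte_rate) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  b0 <- (lo + hi) / 2
  if (abs(rate(b0) - config$target_vte_rate) > 1e-4) {
    stopf("calibrate_intercept: bisection did not reach the target rate")
  }
  b0
}

#' Generate a synthetic lung-cancer cohort
#'
#' Deterministic given the configuration seed. Covariates are drawn per
#' [synthetic_config()]; the VTE outcome is drawn per patient from
#' `logit(p) = b0 + sum(log(OR_f) * active_f)`, where the high-COMPASS-CAT
#' indicator comes from the patient's own generated covariates via the
#' COMPASS-CAT scorer and `b0` is calibrated by [calibrate_intercept()].
#' Event times are exponential with median 2.5 months truncated at
#' follow-up; follow-up is uniform on 1-24 months.
#'
#' @param config a [synthetic_config()].
#' @return a validated cohort of `config$n` patients.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  b0 <- calibrate_intercept(config)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  n <- config$n
  df <- draw_covariates(n, config)
  eta <- if (n > 0) active_factor_eta(df, config$effect_ors) else numeric(0)
  p_vte <- stats::plogis(b0 + eta)
  df$vte <- stats::runif(n) < p_vte
  df$followup_months <- stats::runif(n, 1, 24)
  raw_time <- stats::rexp(n, rate = log(2) / 2.5)
  df$vte_time_months <- ifelse(df$vte, pmin(raw_time, df$followup_months),
                               NA_real_)
  df$death <- stats::runif(n) < config$prevalences[["death"]]
  as_cohort(df, provenance = sprintf("synthetic (seed %d, n %d)",
                                     config$seed, n))
}
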