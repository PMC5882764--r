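#' @name ram_scores
#' @title The four VTE risk assessment models
#'
#' @description
#' Four additive point scores stratify ambulatory lung-cancer patients by
#' their risk of venous thromboembolism:
#'
#' * **KRS** (Khorana risk score): 1 point for the cancer site (lung, always
#'   awarded here), plus 1 point each for pre-chemotherapy platelet count
#'   over 350 x 10^9/L, leukocyte count over 11 x 10^9/L, hemoglobin below
#'   10 g/dL and/or use of erythropoiesis-stimulating agents, and BMI >= 35
#'   kg/m2. High risk at >= 3 points; 0 is low and 1-2 intermediate.
#' * **PROTECHT**: the KRS plus 1 point each for platinum-based and
#'   gemcitabine-based chemotherapy; high risk at >= 3 points.
#' * **CONKO**: the KRS with the BMI item replaced by WHO/ECOG performance
#'   status >= 2 (1 point); high risk at >= 3 points.
#' * **COMPASS-CAT**: a weighted score — anthracycline treatment (6), time
#'   since cancer diagnosis <= 6 months (4), central venous catheter (3),
#'   advanced stage (2), cardiovascular risk-factor composite (5), recent
#'   hospitalization for acute medical illness (5), personal history of VTE
#'   (1), platelet count >= 350 x 10^9/L (2). High risk at >= 7 points,
#'   otherwise low.
#'
#' Threshold strictness is deliberate and asymmetric between models: the
#' KRS-family platelet item fires strictly above 350 while the COMPASS-CAT
#' biomarker fires at >= 350; the 6-month time item fires at <= 6.
#'
#' Each scorer returns a `ram_score` with the point total, the risk
#' category, and a `fired_items` audit trail listing every item that
#' contributed with its points, so any total can be inspected and
#' reconstructed by hand.
NULL

ram_models <- c("KRS", "PROTECHT", "CONKO", "COMPASS_CAT")

new_ram_score <- function(model, fired_items) {
  points <- if (length(fired_items)) sum(unlist(fired_items)) else 0L
  structure(
    list(model = model, points = as.integer(points),
         category = classify_risk(model, points),
         fired_items = fired_items),
    class = "ram_score")
}

#' @export
print.ram_score <- function(x, ...) {
  items <- if (length(x$fired_items)) {
    paste(sprintf("%s=%d", names(x$fired_items),
                  as.integer(unlist(x$fired_items))), collapse = "; ")
  } else "(none)"
  cat(sprintf("<ram_score> %s: %d points (%s)  items: %s\n",
              x$model, x$points, x$category, items))
  invisible(x)
}

#' Risk category for a model and point total
#'
#' Step thresholds: KRS 0 -> low, 1-2 -> intermediate, >= 3 -> high;
#' PROTECHT and CONKO >= 3 -> high, else intermediate (the unconditional
#' lung-site point makes 0 unreachable, so low is never emitted);
#' COMPASS-CAT >= 7 -> high, else low.
#'
#' @param model one of `"KRS"`, `"PROTECHT"`, `"CONKO"`, `"COMPASS_CAT"`.
#' @param points non-negative integer point total (vectorised).
#' @return character vector of `"low"`, `"intermediate"` or `"high"`.
#' @export
classify_risk <- function(model, points) {
  model <- match.arg(model, ram_models)
  if (any(points < 0)) stopf("classify_risk: negative points")
  switch(model,
    KRS = ifelse(points >= 3, "high",
                 ifelse(points >= 1, "intermediate", "low")),
    PROTECHT = ifelse(points >= 3, "high", "intermediate"),
    CONKO = ifelse(points >= 3, "high", "intermediate"),
    COMPASS_CAT = ifelse(points >= 7, "high", "low"))
}

# one-point KRS item indicators shared by the KRS family
krs_item_list <- function(p) {
  list(site_lung = 1L,
       platelets_gt_350 = if (p$platelets > 350) 1L else NULL,
       leukocytes_gt_11 = if (p$leukocytes > 11) 1L else NULL,
       hemoglobin_lt_10_or_esa = if (p$hemoglobin < 10 || p$esa_use) 1L else NULL)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' Khorana risk score for one patient
#' @param patient a single patient row (see [cohort]).
#' @return a `ram_score`.
#' @export
score_khorana <- function(patient) {
  p <- as.list(patient)
  items <- c(krs_item_list(p),
             list(bmi_ge_35 = if (p$bmi_ge_35) 1L else NULL))
  new_ram_score("KRS", drop_null(items))
}

#' PROTECHT score for one patient
#' @inheritParams score_khorana
#' @return a `ram_score`.
#' @export
score_protecht <- function(patient) {
  p <- as.list(patient)
  items <- c(krs_item_list(p),
             list(bmi_ge_35 = if (p$bmi_ge_35) 1L else NULL,
                  platinum_chemo = if (p$platinum_chemo) 1L else NULL,
                  gemcitabine_chemo = if (p$gemcitabine_chemo) 1L else NULL))
  new_ram_score("PROTECHT", drop_null(items))
}

#' CONKO score for one patient
#' @inheritParams score_khorana
#' @return a `ram_score`.
#' @export
score_conko <- function(patient) {
  p <- as.list(patient)
  items <- c(krs_item_list(p),
             list(who_ps_ge_2 = if (p$who_ps >= 2) 1L else NULL))
  new_ram_score("CONKO", drop_null(items))
}

compass_weights <- c(
  anthracycline_chemo = 6L,
  diagnosis_le_6_months = 4L,
  central_venous_catheter = 3L,
  advanced_disease = 2L,
  cardiovascular_risk_factors = 5L,
  recent_hospitalization = 5L,
  personal_vte_history = 1L,
  platelets_ge_350 = 2L
)

#' COMPASS-CAT score for one patient
#' @inheritParams score_khorana
#' @return a `ram_score` (maximum 28 points, high risk at >= 7).
#' @export
score_compass_cat <- function(patient) {
  p <- as.list(patient)
  ind <- c(
    anthracycline_chemo = isTRUE(p$anthracycline_chemo),
    diagnosis_le_6_months = p$months_since_diagnosis <= 6,
    central_venous_catheter = isTRUE(p$central_venous_catheter),
    advanced_disease = is_advanced_disease(p),
    cardiovascular_risk_factors = cardiovascular_composite(p),
    recent_hospitalization = isTRUE(p$recent_hospitalization),
    personal_vte_history = isTRUE(p$personal_vte_history),
    platelets_ge_350 = p$platelets >= 350
  )
  fired <- as.list(compass_weights[ind])
  new_ram_score("COMPASS_CAT", fired)
}

# --- vectorised point totals (independent of the per-record scorers; used
# --- by score_all, the ROC/report pipeline and the synthetic generator) ---

krs_points_vec <- function(df) {
  1L + (df$platelets > 350) + (df$leukocytes > 11) +
    (df$hemoglobin < 10 | df$esa_use) + df$bmi_ge_35
}

protecht_points_vec <- function(df) {
  krs_points_vec(df) + df$platinum_chemo + df$gemcitabine_chemo
}

conko_points_vec <- function(df) {
  1L + (df$platelets > 350) + (df$leukocytes > 11) +
    (df$hemoglobin < 10 | df$esa_use) + (df$who_ps >= 2)
}

compass_points_vec <- function(df) {
  6L * df$anthracycline_chemo +
    4L * (df$months_since_diagnosis <= 6) +
    3L * df$central_venous_catheter +
    2L * is_advanced_disease(df) +
    5L * cardiovascular_composite(df) +
    5L * df$recent_hospitalization +
    1L * df$personal_vte_history +
    2L * (df$platelets >= 350)
}

ram_points_vec <- function(df, model) {
  switch(model,
         KRS = krs_points_vec(df),
         PROTECHT = protecht_points_vec(df),
         CONKO = conko_points_vec(df),
         COMPASS_CAT = compass_points_vec(df))
}

#' Score a whole cohort with all four models
#'
#' Vectorised application of the four scorers; equals the element-wise
#' per-record scorers on every cohort.
#'
#' @param cohort a validated cohort.
#' @param models subset of models to apply (default all four).
#' @return a long `data.frame` with one row per patient x model:
#'   `patient_id`, `model`, `points`, `category`, `fired_items` (semicolon
#'   joined `item=points` tokens).
#' @export
score_all <- function(cohort, models = ram_models) {
  validate_cohort(cohort)
  models <- match.arg(models, ram_models, several.ok = TRUE)
  df <- as.data.frame(cohort)
  out <- lapply(models, function(m) {
    pts <- as.integer(ram_points_vec(df, m))
    data.frame(patient_id = df$patient_id, model = m, points = pts,
               category = classify_risk(m, pts),
               fired_items = fired_items_vec(df, m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  # patient-major order: all models for patient 1, then patient 2, ...
  res <- res[order(match(res$patient_id, df$patient_id),
                   match(res$model, ram_models)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# semicolon-joined "item=points" audit strings, vectorised per model
fired_items_vec <- function(df, model) {
  ind_weights <- switch(model,
    KRS = list(site_lung = rep(TRUE, nrow(df)),
               platelets_gt_350 = df$platelets > 350,
               leukocytes_gt_11 = df$leukocytes > 11,
               hemoglobin_lt_10_or_esa = df$hemoglobin < 10 | df$esa_use,
               bmi_ge_35 = df$bmi_ge_35),
    PROTECHT = list(site_lung = rep(TRUE, nrow(df)),
                    platelets_gt_350 = df$platelets > 350,
                    leukocytes_gt_11 = df$leukocytes > 11,
                    hemoglobin_lt_10_or_esa = df$hemoglobin < 10 | df$esa_use,
                    bmi_ge_35 = df$bmi_ge_35,
                    platinum_chemo = df$platinum_chemo,
                    gemcitabine_chemo = df$gemcitabine_chemo),
    CONKO = list(site_lung = rep(TRUE, nrow(df)),
                 platelets_gt_350 = df$platelets > 350,
                 leukocytes_gt_11 = df$leukocytes > 11,
                 hemoglobin_lt_10_or_esa = df$hemoglobin < 10 | df$esa_use,
                 who_ps_ge_2 = df$who_ps >= 2),
    COMPASS_CAT = list(anthracycline_chemo = df$anthracycline_chemo,
                       diagnosis_le_6_months = df$months_since_diagnosis <= 6,
                       central_venous_catheter = df$central_venous_catheter,
                       advanced_disease = is_advanced_disease(df),
                       cardiovascular_risk_factors = cardiovascular_composite(df),
                       recent_hospitalization = df$recent_hospitalization,
                       personal_vte_history = df$personal_vte_history,
                       platelets_ge_350 = df$platelets >= 350))
  weights <- if (model == "COMPASS_CAT") compass_weights else
    stats::setNames(rep(1L, length(ind_weights)), names(ind_weights))
  mat <- do.call(cbind, ind_weights)
  if (nrow(df) == 0L) return(character(0))
  vapply(seq_len(nrow(df)), function(i) {
    on <- which(mat[i, ])
    if (!length(on)) return("")
    paste(sprintf("%s=%d", names(ind_weights)[on],
                  as.integer(weights[names(ind_weights)[on]])),
          collapse = ";")
  }, character(1))
}
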