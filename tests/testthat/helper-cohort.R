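# Fixture builders used across the suite. All fixtures are built in code.

# One patient with benign defaults: no score items fire except the
# unconditional lung-site point (months_since_diagnosis 8 keeps the
# COMPASS-CAT 6-month item off).
make_patient <- function(patient_id = "P1", ...) {
  p <- data.frame(
    patient_id = patient_id, age = 64L, sex = "male",
    histology = "adenocarcinoma", tnm_stage = "IIIA", who_ps = 1L,
    bmi_ge_35 = FALSE,
    coronary_artery_disease = FALSE, heart_failure = FALSE,
    hyperlipidemia = FALSE, hypertension = FALSE,
    atrial_fibrillation = FALSE, stroke = FALSE,
    peripheral_artery_disease = FALSE, diabetes = FALSE, copd = FALSE,
    asthma = FALSE, chronic_kidney_disease = FALSE, obesity = FALSE,
    history_other_malignancy = FALSE, personal_vte_history = FALSE,
    recent_hospitalization = FALSE,
    platinum_chemo = FALSE, gemcitabine_chemo = FALSE,
    anthracycline_chemo = FALSE, central_venous_catheter = FALSE,
    months_since_diagnosis = 8, esa_use = FALSE,
    platelets = 250, leukocytes = 8, hemoglobin = 13,
    vte = FALSE, vte_time_months = NA_real_, death = FALSE,
    followup_months = 12, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  # keep the BMI/obesity coupling unless a test sets them separately
  if ("bmi_ge_35" %in% names(mods) && !("obesity" %in% names(mods))) {
    p$obesity <- p$bmi_ge_35
  }
  p
}

make_cohort <- function(...) {
  rows <- list(...)
  as_cohort(do.call(rbind, rows), provenance = "test fixture")
}

# Cohort of n patients where a boolean column is TRUE for the first
# `n_flag`, and vte TRUE for given indices. Used to reproduce 2x2 tables
# with prescribed margins.
flag_cohort <- function(n, flag_col, n_flag, vte_idx) {
  rows <- lapply(seq_len(n), function(i) {
    args <- list(patient_id = sprintf("P%03d", i))
    args[[flag_col]] <- i <= n_flag
    if (i %in% vte_idx) {
      args$vte <- TRUE
      args$vte_time_months <- 2.5
    }
    do.call(make_patient, args)
  })
  as_cohort(do.call(rbind, rows), provenance = "test fixture")
}

# 118-patient cohort reproducing the atrial-fibrillation 2x2 of the
# emulated study: 13 with AF of whom 7 developed VTE; 20 events overall.
af_table_cohort <- function() {
  # AF patients 1..13, VTE for AF patients 1..7 and non-AF patients 14..26
  flag_cohort(118, "atrial_fibrillation", 13, c(1:7, 14:26))
}

# Random cohort via the synthetic generator (seeded).
random_cohort <- function(n, seed) {
  generate_cohort(synthetic_config(n = n, seed = seed))
}

# Independent counting oracle for additive one-point scores.
count_true <- function(...) sum(vapply(list(...), isTRUE, logical(1)))
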