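#' @name cohort
#' @title Patient cohort data model
#'
#' @description
#' A cohort is a validated `data.frame` (class `vte_cohort`) with one row per
#' patient and a fixed column schema covering demographics, tumour staging,
#' comorbidity flags, treatment flags, pre-chemotherapy blood counts and the
#' VTE outcome. All risk-score and validation functions in the package take a
#' cohort (or a single patient row from one) as input.
#'
#' Canonical columns, in order:
#' `patient_id` (unique string), `age` (years), `sex` (`"male"`/`"female"`),
#' `histology` (`squamous`, `adenocarcinoma`, `small_cell`, `adenoid_cystic`,
#' `nos`), `tnm_stage` (`IA`, `IB`, `IIA`, `IIB`, `IIIA`, `IIIB`, `IV`, 7th
#' edition), `who_ps` (ECOG/WHO performance status 0-4), `bmi_ge_35`
#' (BMI >= 35 kg/m2), the comorbidity flags `coronary_artery_disease`,
#' `heart_failure`, `hyperlipidemia`, `hypertension`, `atrial_fibrillation`,
#' `stroke`, `peripheral_artery_disease`, `diabetes`, `copd`, `asthma`,
#' `chronic_kidney_disease`, `obesity`, then `history_other_malignancy`,
#' `personal_vte_history`, `recent_hospitalization`, `platinum_chemo`,
#' `gemcitabine_chemo`, `anthracycline_chemo`, `central_venous_catheter`,
#' `months_since_diagnosis`, `esa_use`, `platelets` (10^9/L), `leukocytes`
#' (10^9/L), `hemoglobin` (g/dL), `vte`, `vte_time_months` (only when
#' `vte` is true), `death`, `followup_months`.
#'
#' `obesity` is defined as BMI >= 35 kg/m2 and must agree with `bmi_ge_35`;
#' validation enforces this because the same threshold plays both roles (a
#' Khorana item and a cardiovascular-risk predictor).
NULL

cohort_bool_cols <- c(
  "bmi_ge_35",
  "coronary_artery_disease", "heart_failure", "hyperlipidemia",
  "hypertension", "atrial_fibrillation", "stroke",
  "peripheral_artery_disease", "diabetes", "copd", "asthma",
  "chronic_kidney_disease", "obesity",
  "history_other_malignancy", "personal_vte_history",
  "recent_hospitalization",
  "platinum_chemo", "gemcitabine_chemo", "anthracycline_chemo",
  "central_venous_catheter", "esa_use", "vte", "death"
)

cohort_num_cols <- c(
  "age", "who_ps", "months_since_diagnosis",
  "platelets", "leukocytes", "hemoglobin",
  "vte_time_months", "followup_months"
)

cohort_columns <- c(
  "patient_id", "age", "sex", "histology", "tnm_stage", "who_ps",
  "bmi_ge_35",
  "coronary_artery_disease", "heart_failure", "hyperlipidemia",
  "hypertension", "atrial_fibrillation", "stroke",
  "peripheral_artery_disease", "diabetes", "copd", "asthma",
  "chronic_kidney_disease", "obesity",
  "history_other_malignancy", "personal_vte_history",
  "recent_hospitalization",
  "platinum_chemo", "gemcitabine_chemo", "anthracycline_chemo",
  "central_venous_catheter", "months_since_diagnosis", "esa_use",
  "platelets", "leukocytes", "hemoglobin",
  "vte", "vte_time_months", "death", "followup_months"
)

tnm_stages <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")
histology_levels <- c("squamous", "adenocarcinoma", "small_cell",
                      "adenoid_cystic", "nos")

# The only column allowed to be missing (and only where vte is FALSE).
cohort_optional_cols <- "vte_time_months"

#' Construct and validate a cohort
#'
#' @param x a `data.frame` with the canonical cohort columns (extra columns
#'   are kept but ignored by all analyses).
#' @param provenance free-text source tag stored as an attribute.
#' @return a validated `vte_cohort`.
#' @export
as_cohort <- function(x, provenance = "unspecified") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols) > 0L) {
    stopf("cohort schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  # normalise stage codes ("IIIb" -> "IIIB") and enum case
  x$tnm_stage <- toupper(gsub("[[:space:]]", "", as.character(x$tnm_stage)))
  x$sex <- tolower(as.character(x$sex))
  x$histology <- tolower(as.character(x$histology))
  x$patient_id <- as.character(x$patient_id)
  for (col in cohort_bool_cols) x[[col]] <- parse_bool(x[[col]], col, x$patient_id)
  for (col in cohort_num_cols) {
    if (!is.numeric(x[[col]])) {
      parsed <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(is.na(parsed) & !is.na(x[[col]]) &
                     trimws(as.character(x[[col]])) != "")
      if (length(bad) > 0L) {
        stopf("cohort parse error: field '%s' unparseable for patient_id '%s'",
              col, x$patient_id[bad[1L]])
      }
      x[[col]] <- parsed
    }
  }
  extra <- setdiff(names(x), cohort_columns)
  x <- x[, c(cohort_columns, extra), drop = FALSE]
  class(x) <- c("vte_cohort", "data.frame")
  attr(x, "provenance") <- provenance
  validate_cohort(x)
  x
}

# Parse booleans from logical, 0/1 or "true"/"false" (case-insensitive).
parse_bool <- function(v, col, ids) {
  if (is.logical(v)) {
    out <- v
  } else {
    s <- tolower(trimws(as.character(v)))
    out <- rep(NA, length(s))
    out[s %in% c("1", "true")] <- TRUE
    out[s %in% c("0", "false")] <- FALSE
    bad <- which(is.na(out) & !is.na(v) & s != "" & s != "na")
    if (length(bad) > 0L) {
      stopf("cohort parse error: field '%s' unparseable for patient_id '%s' (value '%s')",
            col, ids[bad[1L]], as.character(v)[bad[1L]])
    }
  }
  out
}

#' Validate a cohort against its invariants
#'
#' Checks column presence, enum values, uniqueness of `patient_id`,
#' positivity of blood counts, agreement of `obesity` with `bmi_ge_35`,
#' absence of `vte_time_months` for patients without VTE, and absence of
#' missing values in mandatory fields. Rows with missing mandatory fields
#' are rejected with a diagnostic naming the patient and field; no silent
#' imputation is performed.
#'
#' @param cohort a `vte_cohort` or compatible `data.frame`.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  x <- cohort
  missing_cols <- setdiff(cohort_columns, names(x))
  if (length(missing_cols) > 0L) {
    stopf("cohort schema error: missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(cohort))
  dup <- x$patient_id[duplicated(x$patient_id)]
  if (length(dup) > 0L) {
    stopf("cohort validation error: duplicate patient_id '%s'", dup[1L])
  }
  mandatory <- setdiff(cohort_columns, cohort_optional_cols)
  for (col in mandatory) {
    bad <- which(is.na(x[[col]]))
    if (length(bad) > 0L) {
      stopf("cohort validation error: missing mandatory field '%s' for patient_id '%s'",
            col, x$patient_id[bad[1L]])
    }
  }
  check_enum <- function(col, levels) {
    bad <- which(!(x[[col]] %in% levels))
    if (length(bad) > 0L) {
      stopf("cohort validation error: field '%s' has invalid value '%s' for patient_id '%s'",
            col, x[[col]][bad[1L]], x$patient_id[bad[1L]])
    }
  }
  check_enum("sex", c("male", "female"))
  check_enum("histology", histology_levels)
  check_enum("tnm_stage", tnm_stages)
  check_enum("who_ps", 0:4)
  for (col in c("platelets", "leukocytes", "hemoglobin")) {
    bad <- which(x[[col]] <= 0)
    if (length(bad) > 0L) {
      stopf("cohort validation error: '%s' must be positive (patient_id '%s')",
            col, x$patient_id[bad[1L]])
    }
  }
  bad <- which(x$age < 18)
  if (length(bad) > 0L) {
    stopf("cohort validation error: age below 18 for patient_id '%s'",
          x$patient_id[bad[1L]])
  }
  bad <- which(x$months_since_diagnosis < 0)
  if (length(bad) > 0L) {
    stopf("cohort validation error: negative months_since_diagnosis for patient_id '%s'",
          x$patient_id[bad[1L]])
  }
  bad <- which(x$followup_months <= 0)
  if (length(bad) > 0L) {
    stopf("cohort validation error: followup_months must be positive (patient_id '%s')",
          x$patient_id[bad[1L]])
  }
  bad <- which(!x$vte & !is.na(x$vte_time_months))
  if (length(bad) > 0L) {
    stopf("cohort validation error: vte_time_months present without VTE for patient_id '%s'",
          x$patient_id[bad[1L]])
  }
  bad <- which(x$obesity != x$bmi_ge_35)
  if (length(bad) > 0L) {
    stopf("cohort validation error: obesity and bmi_ge_35 disagree for patient_id '%s' (both mean BMI >= 35 kg/m2)",
          x$patient_id[bad[1L]])
  }
  invisible(cohort)
}

#' Read a cohort from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row holding the
#' canonical column names (see [cohort]); booleans coded 0/1 (or
#' true/false). Unknown columns are preserved but ignored; row order is
#' preserved.
#'
#' @param path path to the CSV file.
#' @return a validated [as_cohort()] object.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) > 0L) {
    df[df == ""] <- NA
  }
  as_cohort(df, provenance = path)
}

#' Write a cohort to CSV
#'
#' Canonical column order, booleans serialised as 0/1, reals written with
#' full (17 significant digit) precision so that a read/write round trip is
#' the identity on validated cohorts. The optional `vte_time_months` is
#' written empty where absent.
#'
#' @param cohort a validated cohort.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- as.data.frame(cohort)[, cohort_columns, drop = FALSE]
  for (col in cohort_bool_cols) out[[col]] <- as.integer(out[[col]])
  for (col in cohort_num_cols) {
    v <- out[[col]]
    s <- ifelse(is.na(v), NA_character_,
                ifelse(v == round(v) & abs(v) < 1e15,
                       sprintf("%d", as.integer(round(v))),
                       sprintf("%.17g", v)))
    out[[col]] <- s
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Advanced disease under TNM (7th edition)
#'
#' Stages IIIB and IV are considered advanced disease; all earlier stages
#' (including IIIA) are not.
#'
#' @param patient a single patient row or a cohort (vectorised).
#' @return logical, one value per patient.
#' @export
is_advanced_disease <- function(patient) {
  stage <- toupper(gsub("[[:space:]]", "", as.character(patient$tnm_stage)))
  stage %in% c("IIIB", "IV")
}

#' Cardiovascular risk-factor composite
#'
#' True when at least two of the seven predisposing predictors are present:
#' peripheral artery disease, ischemic stroke, coronary artery disease,
#' hypertension, hyperlipidemia, diabetes, obesity. This composite is the
#' 5-point cardiovascular item of the COMPASS-CAT score.
#'
#' @param patient a single patient row or a cohort (vectorised).
#' @return logical, one value per patient.
#' @export
cardiovascular_composite <- function(patient) {
  n <- as.integer(patient$peripheral_artery_disease) +
    as.integer(patient$stroke) +
    as.integer(patient$coronary_artery_disease) +
    as.integer(patient$hypertension) +
    as.integer(patient$hyperlipidemia) +
    as.integer(patient$diabetes) +
    as.integer(patient$obesity)
  n >= 2L
}

#' @export
print.vte_cohort <- function(x, ...) {
  cat(sprintf("<vte_cohort> %d patients, %d with VTE (%.1f%%)  [source: %s]\n",
              nrow(x), sum(x$vte),
              if (nrow(x) > 0) 100 * mean(x$vte) else NA_real_,
              attr(x, "provenance") %||% "unspecified"))
  invisible(x)
}
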