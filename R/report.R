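#' Run the full VTE risk-model validation pipeline
#'
#' Scores every patient with the four risk models, stratifies the cohort by
#' risk category with VTE rates per group, computes the high-vs-rest
#' diagnostic metrics and the C statistic of each model, screens the
#' candidate risk factors against the outcome, fits the multivariate
#' logistic model over the univariate-significant factors, and derives the
#' ROC curve and Youden-optimal cutoff of the COMPASS-CAT point score.
#' Every sub-result is identical to calling the stage function directly.
#' Non-fatal problems (non-estimable factors, separation) are flagged in
#' the relevant tables; the analysis continues past them.
#'
#' @param cohort a validated cohort with at least one event and one
#'   non-event.
#' @param alpha_in univariate p-value threshold for multivariate entry
#'   (default 0.01).
#' @param factors named predicate list for the univariate screen
#'   (default [default_screen_factors()]).
#' @return an object of class `vte_report`; see Details for components.
#'
#' @details Components: `summary` (n, VTE count, VTE rate %),
#' `stratification` (per model x category: n, VTE n, VTE rate %),
#' `diagnostics` (per model: tp/fn/fp/tn, sensitivity/specificity/PPV/NPV
#' in percent, C statistic), `univariate` (screen table), `multivariate`
#' (logistic fit, or the error message when no factor qualifies),
#' `roc` (COMPASS-CAT points ROC with AUC, SE and optimal cutoff), and
#' `meta` (package version, timestamp). All stored proportions are full
#' precision; percent columns apply half-up rounding for presentation.
#' @export
run_analysis <- function(cohort, alpha_in = 0.01,
                         factors = default_screen_factors()) {
  validate_cohort(cohort)
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (n == 0L) stopf("run_analysis: empty cohort")
  n_vte <- sum(df$vte)
  if (n_vte == 0L || n_vte == n) {
    stopf("run_analysis: degenerate outcome (%d events of %d patients)",
          n_vte, n)
  }

  scores <- score_all(cohort)

  strat <- do.call(rbind, lapply(ram_models, function(m) {
    s <- scores[scores$model == m, ]
    cats <- intersect(c("low", "intermediate", "high"), unique(s$category))
    do.call(rbind, lapply(cats, function(cc) {
      idx <- s$category == cc
      grp_n <- sum(idx)
      grp_vte <- sum(df$vte[match(s$patient_id[idx], df$patient_id)])
      data.frame(model = m, category = cc, n = grp_n, vte_n = grp_vte,
                 vte_rate_pct = as_pct(grp_vte / grp_n, 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(strat) <- NULL

  diagnostics <- do.call(rbind, lapply(ram_models, function(m) {
    pts <- ram_points_vec(df, m)
    high <- classify_risk(m, pts) == "high"
    t <- two_by_two(a = sum(high & df$vte), b = sum(!high & df$vte),
                    c = sum(high & !df$vte), d = sum(!high & !df$vte))
    dm <- diagnostic_metrics(t)
    cstat <- roc_curve(pts, df$vte)$auc
    data.frame(model = m, tp = dm$tp, fn = dm$fn, fp = dm$fp, tn = dm$tn,
               sensitivity_pct = as_pct(dm$sensitivity),
               specificity_pct = as_pct(dm$specificity),
               ppv_pct = as_pct(dm$ppv), npv_pct = as_pct(dm$npv),
               c_statistic = cstat, stringsAsFactors = FALSE)
  }))
  rownames(diagnostics) <- NULL

  screen <- univariate_screen(cohort, factors)

  multivariate <- tryCatch(
    suppressWarnings(multivariate_model(cohort, screen, alpha_in = alpha_in)),
    error = function(e) structure(list(error = conditionMessage(e)),
                                  class = "logistic_fit_unavailable"))

  compass_pts <- compass_points_vec(df)
  roc <- roc_curve(compass_pts, df$vte)
  cutoff <- optimal_cutoff(roc)

  structure(list(
    summary = list(n = n, vte_n = n_vte, vte_rate_pct = as_pct(n_vte / n, 1)),
    scores = scores,
    stratification = strat,
    diagnostics = diagnostics,
    univariate = screen,
    multivariate = multivariate,
    roc = list(thresholds = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr,
               auc = roc$auc, auc_se = roc$auc_se,
               cutoff = cutoff$cutoff,
               cutoff_sensitivity = cutoff$sensitivity,
               cutoff_specificity = cutoff$specificity),
    meta = list(package_version = as.character(utils::packageVersion("vteram")),
                alpha_in = alpha_in,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "vte_report")
}

#' @export
print.vte_report <- function(x, ...) {
  cat(sprintf("<vte_report> %d patients, %d VTE events (%.1f%%)\n",
              x$summary$n, x$summary$vte_n, x$summary$vte_rate_pct))
  cat("\nRisk stratification (VTE rate % per group):\n")
  print(x$stratification, row.names = FALSE)
  cat("\nDiagnostic performance of the high-risk groups:\n")
  print(x$diagnostics, row.names = FALSE, digits = 3)
  cat("\nUnivariate screen:\n")
  print(x$univariate[, c("factor", "a", "b", "c", "d", "or", "ci_low",
                         "ci_high", "p_value", "estimable",
                         "separation_inducing")],
        row.names = FALSE, digits = 3)
  cat("\nMultivariate model:\n")
  if (inherits(x$multivariate, "logistic_fit_unavailable")) {
    cat("  unavailable:", x$multivariate$error, "\n")
  } else {
    print(x$multivariate)
    excl <- attr(x$multivariate, "excluded")
    if (length(excl)) {
      cat("  excluded:",
          paste(sprintf("%s (%s)", names(excl), excl), collapse = "; "), "\n")
    }
  }
  cat(sprintf("\nCOMPASS-CAT ROC: AUC %.3f (SE %.3f), Youden cutoff %g (sens %.0f%%, spec %.0f%%)\n",
              x$roc$auc, x$roc$auc_se, x$roc$cutoff,
              100 * x$roc$cutoff_sensitivity, 100 * x$roc$cutoff_specificity))
  invisible(x)
}

# Convert a report to plain lists for JSON serialisation.
report_to_list <- function(report) {
  mv <- report$multivariate
  mv_out <- if (inherits(mv, "logistic_fit_unavailable")) {
    list(available = FALSE, error = mv$error)
  } else {
    list(available = TRUE,
         terms = mv$terms, beta = mv$beta, se = mv$se,
         or = mv$or_point, ci_low = mv$ci_low, ci_high = mv$ci_high,
         p_value = mv$p_value, log_likelihood = mv$log_likelihood,
         converged = mv$converged,
         separation_detected = mv$separation_detected,
         selected = attr(mv, "selected"),
         excluded = as.list(attr(mv, "excluded")))
  }
  uni <- report$univariate
  attr(uni, "factors") <- NULL
  list(summary = report$summary,
       stratification = report$stratification,
       diagnostics = report$diagnostics,
       univariate = uni,
       multivariate = mv_out,
       roc = report$roc,
       meta = report$meta)
}

#' Write an analysis report as JSON
#'
#' Full-precision serialisation; re-running the analysis on the same input
#' yields byte-identical JSON apart from the timestamp field.
#'
#' @param report a `vte_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "vte_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' Write an analysis report as human-readable text
#'
#' @param report a `vte_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_text <- function(report, path) {
  stopifnot(inherits(report, "vte_report"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  sink(con)
  on.exit(sink(), add = TRUE, after = FALSE)
  print(report)
  invisible(path)
}
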