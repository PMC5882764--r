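#' Logistic regression with Wald odds ratios
#'
#' Maximum-likelihood binomial fit (iteratively reweighted least squares,
#' at most 100 iterations, tight convergence tolerance) returning, per
#' term, the coefficient, its standard error from the inverse observed
#' information, the odds ratio `exp(beta)` and its Wald 95% interval
#' `exp(beta +/- 1.96 se)`. Quasi-complete or complete separation — some
#' fitted probability within 1e-6 of 0 or 1 together with a diverging
#' coefficient — is detected and flagged with a warning: the fit is
#' returned, but its coefficients must not be trusted.
#'
#' @param design data.frame of predictors (binary/logical or numeric), one
#'   row per patient; a zero-column data.frame fits the intercept-only
#'   model, whose fitted probability is the event fraction.
#' @param outcome logical (or 0/1) event indicator; both classes required.
#' @return an object of class `logistic_fit`: `terms`, `beta`, `se`,
#'   `or_point`, `ci_low`, `ci_high`, `p_value` (Wald), `log_likelihood`,
#'   `converged`, `separation_detected`, `n`.
#' @export
fit_logistic <- function(design, outcome) {
  stopifnot(is.data.frame(design))
  y <- as.logical(outcome)
  stopifnot(length(y) >= 1L, !anyNA(y))
  if (ncol(design) >= 1L) stopifnot(length(y) == nrow(design))
  if (all(y) || !any(y)) {
    stopf("fit_logistic: both outcome classes must be present")
  }
  if (ncol(design) >= 1L) {
    dat <- as.data.frame(lapply(design, as.numeric))
    dat$.outcome <- as.numeric(y)
    fml <- .outcome ~ .
  } else {
    dat <- data.frame(.outcome = as.numeric(y))
    fml <- .outcome ~ 1
  }
  fit <- stats::glm(fml, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  p <- sm$coefficients[, "Pr(>|z|)"]
  fitted <- stats::fitted(fit)
  separation <- length(beta) > 1L &&
    any(fitted < 1e-6 | fitted > 1 - 1e-6) &&
    max(abs(beta[-1L])) > 10
  if (separation) {
    warning("fit_logistic: separation detected; coefficients not trusted",
            call. = FALSE)
  }
  if (!fit$converged && !separation) {
    stopf("fit_logistic: IRLS failed to converge in 100 iterations (deviance %.6g)",
          fit$deviance)
  }
  structure(list(
    terms = names(beta),
    beta = unname(beta),
    se = unname(se),
    or_point = unname(exp(beta)),
    ci_low = unname(exp(beta - 1.96 * se)),
    ci_high = unname(exp(beta + 1.96 * se)),
    p_value = unname(p),
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = fit$converged,
    separation_detected = separation,
    n = nrow(design)), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, logLik = %.3f%s\n", x$n,
              x$log_likelihood,
              if (x$separation_detected) "  [SEPARATION DETECTED]" else ""))
  tab <- data.frame(term = x$terms, beta = x$beta, se = x$se,
                    OR = x$or_point, ci_low = x$ci_low, ci_high = x$ci_high,
                    p = x$p_value)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Univariate screen of candidate VTE risk factors
#'
#' For each named factor, tabulates the factor against the VTE outcome and
#' reports the cross-product odds ratio with its Woolf interval
#' ([odds_ratio_2x2()]) and the Pearson chi-square p-value
#' ([chi_square_test()]). A factor that is constant in the cohort, or whose
#' table is degenerate, is returned as a flagged non-estimable row; the
#' screen never aborts. A zero cell among the event rows (`b = 0` or
#' `c = 0` with the corrected OR) marks the factor `separation_inducing`
#' for downstream multivariate selection.
#'
#' @param cohort a validated cohort with VTE outcomes.
#' @param factors named list of vectorised predicates (functions of the
#'   cohort data.frame returning one logical per patient).
#' @return a `data.frame`, one row per factor, in the given order:
#'   cell counts, `or`, `ci_low`, `ci_high`, `log_or_se`, `p_value`,
#'   `estimable`, `correction_applied`, `separation_inducing`. The factor
#'   list is attached as `attr(, "factors")` for [multivariate_model()].
#' @export
univariate_screen <- function(cohort, factors) {
  validate_cohort(cohort)
  stopifnot(length(factors) >= 1L, !is.null(names(factors)),
            all(nzchar(names(factors))))
  rows <- lapply(names(factors), function(nm) {
    row <- data.frame(factor = nm, a = NA_integer_, b = NA_integer_,
                      c = NA_integer_, d = NA_integer_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      log_or_se = NA_real_, p_value = NA_real_,
                      estimable = FALSE, correction_applied = FALSE,
                      separation_inducing = FALSE,
                      stringsAsFactors = FALSE)
    tryCatch({
      t <- build_two_by_two(cohort, factors[[nm]], function(df) df$vte)
      row$a <- t$a; row$b <- t$b; row$c <- t$c; row$d <- t$d
      if ((t$a + t$c) == 0L || (t$b + t$d) == 0L) {
        return(row)  # constant factor: non-estimable
      }
      orr <- odds_ratio_2x2(t)
      row$or <- orr$or_point; row$ci_low <- orr$ci_low
      row$ci_high <- orr$ci_high; row$log_or_se <- orr$log_or_se
      row$estimable <- orr$estimable
      row$correction_applied <- orr$correction_applied
      row$separation_inducing <- (t$b == 0L || t$c == 0L)
      row$p_value <- tryCatch(chi_square_test(t)$p_value,
                              error = function(e) NA_real_)
      row
    }, error = function(e) row)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "factors") <- factors
  out
}

#' Multivariate logistic model over univariate-significant factors
#'
#' Retains the factors whose univariate chi-square p-value is below
#' `alpha_in`, dropping non-estimable factors and factors that would induce
#' separation (a factor present in all — or no — patients with events);
#' exclusions are recorded in the result. The survivors enter a joint
#' [fit_logistic()].
#'
#' @param cohort the cohort on which `screen` was computed.
#' @param screen the result of [univariate_screen()] (carries the factor
#'   predicates).
#' @param alpha_in inclusion threshold on the univariate p-value
#'   (default 0.01).
#' @return a `logistic_fit` with attributes `selected` (factor names
#'   entered) and `excluded` (named character vector of exclusion reasons).
#' @export
multivariate_model <- function(cohort, screen, alpha_in = 0.01) {
  validate_cohort(cohort)
  factors <- attr(screen, "factors")
  if (is.null(factors)) {
    stopf("multivariate_model: screen carries no factor predicates; compute it with univariate_screen()")
  }
  excluded <- character(0)
  selected <- character(0)
  for (i in seq_len(nrow(screen))) {
    nm <- screen$factor[i]
    if (!isTRUE(screen$estimable[i])) {
      excluded[nm] <- "non-estimable"
    } else if (isTRUE(screen$separation_inducing[i])) {
      excluded[nm] <- "separation-inducing (zero cell among events or non-events)"
    } else if (is.na(screen$p_value[i]) || screen$p_value[i] >= alpha_in) {
      # not significant; silently not selected
    } else {
      selected <- c(selected, nm)
    }
  }
  if (length(selected) == 0L) {
    stopf("multivariate_model: no factor passes p < %g; consider raising alpha_in",
          alpha_in)
  }
  df <- as.data.frame(cohort)
  design <- as.data.frame(lapply(factors[selected],
                                 function(f) as.numeric(f(df))))
  names(design) <- selected
  fit <- fit_logistic(design, df$vte)
  attr(fit, "selected") <- selected
  attr(fit, "excluded") <- excluded
  fit
}

#' Default univariate factor list
#'
#' The candidate risk factors screened against the VTE outcome in the
#' validation pipeline: a high COMPASS-CAT score, gemcitabine-based
#' chemotherapy, atrial fibrillation, recent hospitalization for acute
#' medical illness, chronic kidney disease, and advanced disease.
#'
#' @return named list of vectorised predicates for [univariate_screen()].
#' @export
default_screen_factors <- function() {
  list(
    high_compass_cat = function(df) compass_points_vec(df) >= 7,
    gemcitabine_chemo = function(df) df$gemcitabine_chemo,
    atrial_fibrillation = function(df) df$atrial_fibrillation,
    recent_hospitalization = function(df) df$recent_hospitalization,
    chronic_kidney_disease = function(df) df$chronic_kidney_disease,
    advanced_disease = function(df) is_advanced_disease(df)
  )
}
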