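#' 2x2 exposure-by-outcome table
#'
#' Cell convention: `a` = exposed with event, `b` = unexposed with event,
#' `c` = exposed without event, `d` = unexposed without event. When the
#' exposure is "test positive" (a high risk-score category), `a`, `b`, `c`,
#' `d` are the true positives, false negatives, false positives and true
#' negatives respectively.
#'
#' @param a,b,c,d non-negative integer cell counts, `a+b+c+d >= 1`.
#' @return an object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stopf("two_by_two: cells must be non-negative integers")
  }
  if (sum(cells) < 1) stopf("two_by_two: empty table")
  cells <- stats::setNames(as.integer(round(cells)), c("a", "b", "c", "d"))
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("event", "no event"),
                              c("exposed", "unexposed")))
  cat("<two_by_two>\n")
  print(m)
  invisible(x)
}

#' Tabulate a cohort into a 2x2 table
#'
#' @param cohort a validated cohort.
#' @param exposure,outcome vectorised predicates: functions taking the
#'   cohort data.frame and returning one logical per patient (e.g.
#'   `function(df) df$atrial_fibrillation`).
#' @return a [two_by_two()] whose four cells partition the cohort.
#' @export
build_two_by_two <- function(cohort, exposure, outcome) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0L) stopf("build_two_by_two: empty cohort")
  df <- as.data.frame(cohort)
  e <- as.logical(exposure(df))
  o <- as.logical(outcome(df))
  stopifnot(length(e) == nrow(df), length(o) == nrow(df),
            !anyNA(e), !anyNA(o))
  two_by_two(a = sum(e & o), b = sum(!e & o),
             c = sum(e & !o), d = sum(!e & !o))
}

#' Diagnostic metrics of a risk classifier
#'
#' Interprets the 2x2 table with exposure = test positive: sensitivity
#' `tp/(tp+fn)` (probability of a high score among patients with VTE),
#' specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. A
#' metric whose denominator is zero is returned as `NA` and named in
#' `undefined`, never silently zero. Exact (Clopper-Pearson) binomial 95%
#' intervals accompany each defined metric.
#'
#' @param t a [two_by_two()] with at least one event and one non-event.
#' @return an object of class `diagnostic_metrics` with counts (`tp`, `fn`,
#'   `fp`, `tn`), the four proportions, their intervals, and `undefined`.
#' @export
diagnostic_metrics <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  tp <- t$a; fn <- t$b; fp <- t$c; tn <- t$d
  if (tp + fn == 0L || fp + tn == 0L) {
    stopf("diagnostic_metrics: need at least one event and one non-event")
  }
  ratio <- function(num, den) if (den > 0L) num / den else NA_real_
  ci <- function(num, den) {
    if (den == 0L) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(num, den)$conf.int)
  }
  m <- list(tp = tp, fn = fn, fp = fp, tn = tn,
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn),
            sensitivity_ci = ci(tp, tp + fn),
            specificity_ci = ci(tn, tn + fp),
            ppv_ci = ci(tp, tp + fp),
            npv_ci = ci(tn, tn + fn))
  m$undefined <- names(which(vapply(
    m[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  structure(m, class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 0, ...) {
  f <- function(p) if (is.na(p)) "undefined" else
    sprintf("%s%%", format(as_pct(p, digits)))
  cat(sprintf(
    "<diagnostic_metrics> tp=%d fn=%d fp=%d tn=%d\n  sensitivity %s, specificity %s, PPV %s, NPV %s\n",
    x$tp, x$fn, x$fp, x$tn, f(x$sensitivity), f(x$specificity),
    f(x$ppv), f(x$npv)))
  invisible(x)
}

#' Cross-product odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad/bc`, `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`, interval
#' `exp(log OR +/- 1.96 SE)`. If any cell is zero, 0.5 is added to all four
#' cells first (Haldane-Anscombe) and `correction_applied` is set. A table
#' with both cells of a diagonal zero is flagged non-estimable.
#'
#' @param t a [two_by_two()] with total count >= 4.
#' @return an object of class `odds_ratio_result` with `or_point`,
#'   `ci_low`, `ci_high`, `log_or_se`, `correction_applied`, `estimable`.
#' @export
odds_ratio_2x2 <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (sum(cells) < 4) stopf("odds_ratio_2x2: total count must be >= 4")
  non_estimable <- (t$a == 0L && t$d == 0L) || (t$b == 0L && t$c == 0L)
  correction <- any(cells == 0L)
  res <- list(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              log_or_se = NA_real_, correction_applied = correction,
              estimable = !non_estimable)
  if (!non_estimable) {
    cc <- cells + if (correction) 0.5 else 0
    lor <- log(cc[1]) + log(cc[4]) - log(cc[2]) - log(cc[3])
    se <- sqrt(sum(1 / cc))
    res$or_point <- exp(lor)
    res$ci_low <- exp(lor - 1.96 * se)
    res$ci_high <- exp(lor + 1.96 * se)
    res$log_or_se <- se
  }
  structure(res, class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  if (!x$estimable) {
    cat("<odds_ratio_result> non-estimable (two zero cells on a diagonal)\n")
  } else {
    cat(sprintf("<odds_ratio_result> OR %.2f (95%% CI %.2f-%.2f)%s\n",
                x$or_point, x$ci_low, x$ci_high,
                if (x$correction_applied) "  [Haldane-Anscombe +0.5]" else ""))
  }
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson X^2 without continuity correction, p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param t a [two_by_two()] with all margins positive.
#' @return list with `statistic` and `p_value`.
#' @export
chi_square_test <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- matrix(c(t$a, t$b, t$c, t$d), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stopf("chi_square_test: degenerate margin (all events or none, or constant exposure)")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Mann-Whitney U test
#'
#' U with midrank tie handling. Two-sided p-value by exact enumeration of
#' all group-label assignments when both samples have at most `exact_max`
#' observations (ties allowed), otherwise by the normal approximation with
#' the tie-corrected variance, no continuity correction.
#'
#' @param x,y non-empty numeric samples; `u` is reported for `x`.
#' @param exact_max largest per-sample size for the exact branch (default 8).
#' @return list with `u`, `p_value`, `method` (`"exact"` or `"normal"`),
#'   and `degenerate` (TRUE when every value in both samples is identical,
#'   in which case `p_value` is 1).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L, !anyNA(x), !anyNA(y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L) {
    return(list(u = u_obs, p_value = 1, method = "degenerate",
                degenerate = TRUE))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(u = u_obs, p_value = p, method = method, degenerate = FALSE)
}
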