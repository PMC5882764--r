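#' ROC curve with C statistic
#'
#' One operating point per distinct score value, thresholds descending,
#' using the "score >= threshold is test positive" rule; an initial
#' `Inf` threshold anchors the curve at (0, 0) and the lowest score ends it
#' at (1, 1). The area under the curve is the trapezoidal integral of TPR
#' over FPR, which for a step curve equals the tie-inclusive Mann-Whitney
#' concordance: the probability that a random event patient outscores a
#' random non-event patient, ties counted 1/2 (the C statistic). The
#' standard error of the area uses the Hanley-McNeil formula.
#'
#' @param scores numeric score per patient.
#' @param labels logical (or 0/1) event indicator per patient; both classes
#'   must be present.
#' @return an object of class `roc_curve` with `thresholds`, `tpr`, `fpr`,
#'   `auc`, `auc_se`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("roc_curve: both outcome classes must be present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                    (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = auc, auc_se = auc_se,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.3f (SE %.3f), %d events / %d non-events\n",
              length(x$thresholds), x$auc, x$auc_se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Picks the finite threshold maximising Youden's J = sensitivity +
#' specificity - 1; ties are broken toward the higher threshold (fewer
#' test-positives). Patients at or above the cutoff are test positive.
#'
#' @param roc a [roc_curve()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  finite <- is.finite(roc$thresholds)
  j <- roc$tpr[finite] - roc$fpr[finite]
  thr <- roc$thresholds[finite]
  best <- which.max(j)  # thresholds descending: first max = highest threshold
  list(cutoff = thr[best],
       sensitivity = roc$tpr[finite][best],
       specificity = 1 - roc$fpr[finite][best],
       youden_j = j[best])
}
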