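#' Confusion-matrix metrics at a score threshold
#'
#' Binarizes scores at `threshold`, fills the confusion matrix and evaluates
#' the standard binary-classification metrics: accuracy, sensitivity
#' (recall), specificity, precision, F1 and the Matthews correlation
#' coefficient. A zero MCC denominator yields MCC = 0 (documented
#' convention for degenerate confusion matrices).
#'
#' @param labels Binary labels (0/1 or `"positive"`/`"negative"`).
#' @param scores Numeric scores or probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return A list of class `khib_metrics` with `TP`, `TN`, `FP`, `FN`,
#'   `ACC`, `SN`, `SP`, `PR`, `F1`, `MCC`, `threshold`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  y <- normalize_labels(labels)
  stopifnot(length(y) == length(scores), length(y) > 0)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & y == 1)
  TN <- sum(pred == 0 & y == 0)
  FP <- sum(pred == 1 & y == 0)
  FN <- sum(pred == 0 & y == 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  PR <- safe_div(TP, TP + FP)
  SN <- safe_div(TP, TP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    ACC = (TP + TN) / (TP + TN + FP + FN),
    SN = SN,
    SP = safe_div(TN, TN + FP),
    PR = PR,
    F1 = safe_div(2 * PR * SN, PR + SN),
    MCC = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den,
    threshold = threshold), class = "khib_metrics")
}

#' ROC curve and AUC
#'
#' AUC is computed as the normalized Mann-Whitney U statistic (tied scores
#' count one half), which is identical to trapezoidal integration of the
#' step ROC curve. The returned curve starts at (0, 0), ends at (1, 1) and
#' is monotone in both axes.
#'
#' @inheritParams confusion_metrics
#' @return A list with `auc`, `se` (Hanley-McNeil standard error) and
#'   `curve` (data frame of `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(labels, scores) {
  y <- normalize_labels(labels)
  stopifnot(length(y) == length(scores))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # step ROC over unique score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE)     # last point of each tie block
  tpr <- cumsum(ys == 1)[keep] / n1
  fpr <- cumsum(ys == 0)[keep] / n0
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, ss[keep]))
  list(auc = auc, se = auc_se_hanley(auc, n1, n0), curve = curve)
}

# Hanley-McNeil (1982) standard error of an AUC.
auc_se_hanley <- function(A, n_pos, n_neg) {
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_pos - 1) * (Q1 - A^2) + (n_neg - 1) * (Q2 - A^2)) /
         (n_pos * n_neg))
}

#' Hanley-McNeil comparison of two correlated AUCs
#'
#' Tests the difference between the AUCs of two score vectors measured on
#' the same samples. Each AUC's standard error uses the Hanley-McNeil
#' formula; the correlation term `r` is estimated as the mean of the
#' within-positives and within-negatives Pearson correlations of the two
#' score vectors (a continuous surrogate for the original table lookup).
#' The z statistic is antisymmetric in the two score vectors; the p-value is
#' two-sided normal.
#'
#' @param labels Binary labels.
#' @param scores_a,scores_b Two score vectors on the same samples.
#' @return A list with `auc_a`, `auc_b`, `se_a`, `se_b`, `r`, `z`, `p`.
#' @export
hanley_mcneil_compare <- function(labels, scores_a, scores_b) {
  y <- normalize_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("score vectors must cover the same samples as the labels")
  }
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  A <- roc_auc(y, scores_a)$auc
  B <- roc_auc(y, scores_b)$auc
  se_a <- auc_se_hanley(A, n1, n0)
  se_b <- auc_se_hanley(B, n1, n0)
  r_pos <- stats::cor(scores_a[y == 1], scores_b[y == 1])
  r_neg <- stats::cor(scores_a[y == 0], scores_b[y == 0])
  r <- mean(c(r_pos, r_neg))
  if (is.na(r)) r <- 0               # constant scores within a class
  den <- sqrt(max(0, se_a^2 + se_b^2 - 2 * r * se_a * se_b))
  z <- if (den == 0) 0 else (A - B) / den
  list(auc_a = A, auc_b = B, se_a = se_a, se_b = se_b, r = r,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Full metric report for one score vector
#'
#' Convenience wrapper combining [confusion_metrics()] and [roc_auc()].
#'
#' @inheritParams confusion_metrics
#' @return A list with the confusion metrics plus `AUC`, `AUC_se` and the
#'   ROC `curve`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5) {
  cm <- confusion_metrics(labels, scores, threshold)
  roc <- roc_auc(labels, scores)
  c(unclass(cm), list(AUC = roc$auc, AUC_se = roc$se, curve = roc$curve))
}
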