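#' ROC curve with trapezoidal AUC
#'
#' Tied scores are grouped into single threshold steps (diagonal segments),
#' which makes the trapezoidal AUC equal to the concordant-pair
#' (Mann-Whitney) statistic with half credit for cross-class ties.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Class labels, `"positive"` / `"negative"` (or a logical
#'   vector, `TRUE` = positive).
#' @return Object of class `roc_result`: `points` (threshold, fpr, tpr)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0L || N == 0L) stop("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  ends <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(p)[ends]
  fp <- cumsum(!p)[ends]
  points <- data.frame(threshold = c(Inf, s[ends]),
                       fpr = c(0, fp / N),
                       tpr = c(0, tp / P))
  auc <- .trapezoid(points$fpr, points$tpr)
  structure(list(points = points, auc = auc), class = "roc_result")
}

.trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d points)\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' Normalized partial AUC
#'
#' Area under the ROC curve restricted to false positive rates in
#' `[0, max_fpr]`, divided by `max_fpr`, so a perfect classifier scores
#' 1.0 at every cutoff and `pauc(roc, 1) == auc`.
#'
#' @param roc A [roc_curve()] result.
#' @param max_fpr FPR cutoff in (0, 1\].
#' @return Normalized partial AUC in \[0, 1\].
#' @export
pauc <- function(roc, max_fpr) {
  stopifnot(max_fpr > 0, max_fpr <= 1)
  fpr <- roc$points$fpr
  tpr <- roc$points$tpr
  keep <- fpr <= max_fpr
  x <- fpr[keep]
  y <- tpr[keep]
  if (max(x) < max_fpr) {
    # interpolate the curve at the cutoff
    i <- which(fpr > max_fpr)[1L]
    frac <- (max_fpr - fpr[i - 1L]) / (fpr[i] - fpr[i - 1L])
    x <- c(x, max_fpr)
    y <- c(y, tpr[i - 1L] + frac * (tpr[i] - tpr[i - 1L]))
  }
  .trapezoid(x, y) / max_fpr
}

#' Confusion counts at a decision threshold
#'
#' @param scores Numeric prediction scores.
#' @param labels Class labels (`"positive"` / `"negative"` or logical).
#' @param threshold Scores `>= threshold` are predicted positive.
#' @return Named integer vector `(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  pred <- scores >= threshold
  c(TP = sum(pred & pos), FP = sum(pred & !pos),
    TN = sum(!pred & !pos), FN = sum(!pred & pos))
}

#' Matthews correlation coefficient
#'
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; 0 when any
#' factor of the denominator is 0.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]])
  fn <- as.numeric(counts[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' F-measure (harmonic mean of precision and recall)
#'
#' `2 precision recall / (precision + recall)` with
#' `precision = TP / (TP + FP)` and `recall = TP / (TP + FN)`; 0 when
#' `TP = 0`.
#'
#' @param counts Named vector with `TP`, `FP`, `FN` (and `TN`, unused).
#' @return F-measure in \[0, 1\].
#' @export
f_measure <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  if (tp == 0) return(0)
  precision <- tp / (tp + as.numeric(counts[["FP"]]))
  recall <- tp / (tp + as.numeric(counts[["FN"]]))
  2 * precision * recall / (precision + recall)
}

#' Select the decision threshold maximizing the F-measure
#'
#' Scans every distinct score as a candidate threshold (prediction rule:
#' score `>=` threshold); ties in the F-measure are broken toward the
#' smallest threshold.
#'
#' @param scores Numeric prediction scores (e.g. pooled cross-validation
#'   scores).
#' @param labels Class labels.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  P <- sum(pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  ends <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(p)[ends]
  fp <- cumsum(!p)[ends]
  fn <- P - tp
  f <- ifelse(tp == 0, 0, 2 * tp / (2 * tp + fp + fn))
  best <- max(which(f == max(f)))   # scores sorted desc: last max = smallest
  s[ends[best]]
}

#' Equal-variance two-sample t-test on per-fold AUCs
#'
#' @param aucs1,aucs2 Numeric vectors of per-fold AUC values (length >= 2).
#' @return Two-sided p-value. When both samples have zero variance the
#'   p-value is 1 for equal means and 0 otherwise.
#' @export
compare_auc_ttest <- function(aucs1, aucs2) {
  stopifnot(length(aucs1) >= 2L, length(aucs2) >= 2L)
  if (stats::sd(aucs1) == 0 && stats::sd(aucs2) == 0) {
    return(if (mean(aucs1) == mean(aucs2)) 1 else 0)
  }
  stats::t.test(aucs1, aucs2, var.equal = TRUE)$p.value
}
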