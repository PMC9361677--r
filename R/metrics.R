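#' Classification metrics from a confusion table
#'
#' Evaluates accuracy, precision, recall, F1 and the Matthews correlation
#' coefficient (MCC) from the four cells of a binary confusion table.
#'
#' Zero-denominator conventions: precision (and analogously recall/F1) with an
#' empty denominator is reported as 0 with a warning; MCC with any zero factor
#' under the square root is reported as 0, the standard convention that keeps
#' fold averages finite.
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return A named list with elements `accuracy`, `precision`, `recall`, `f1`
#'   and `mcc`.
#' @examples
#' confusion_metrics(tp = 40, tn = 30, fp = 10, fn = 20)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  n <- tp + tn + fp + fn
  if (n == 0L) stop("all confusion counts are zero")

  accuracy <- (tp + tn) / n
  precision <- if (tp + fp == 0) {
    warning("precision undefined (tp + fp = 0); reporting 0")
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("recall undefined (tp + fn = 0); reporting 0")
    0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  denom2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)

  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, mcc = mcc)
}

#' Mean squared error
#'
#' `(1/n) * sum((truth - pred)^2)`. In classification reports the package
#' passes predicted class-1 probabilities against the 0/1 labels (a Brier
#' score), which is the reading consistent with probabilistic classifiers.
#'
#' @param truth,pred Numeric vectors of equal length.
#' @return A single non-negative number.
#' @export
mse <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (length(truth) == 0L) stop("empty input")
  mean((truth - pred)^2)
}

#' ROC curve and AUC
#'
#' AUC is computed with the rank (Mann-Whitney) formulation using midranks for
#' tied scores, which is exactly the trapezoidal area under the empirical ROC
#' curve. ROC points (FPR, TPR) at every distinct threshold are returned for
#' plotting.
#'
#' @param labels Binary vector (0/1 or logical); both classes must be present.
#' @param scores Numeric scores, larger meaning more confidently positive.
#' @return List with `auc` (scalar) and `curve` (data.frame with columns
#'   `fpr`, `tpr`, `threshold`).
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))$auc  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores lengths differ")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present for AUC")
  if (any(!is.finite(scores))) stop("non-finite scores")

  # Mann-Whitney with midranks
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied thresholds
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]
  fp <- cumsum(1L - y)[keep]
  curve <- data.frame(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, s[keep])
  )
  list(auc = auc, curve = curve)
}

#' Metrics from labels, predicted classes and scores
#'
#' Convenience wrapper used by the cross-validation driver: builds the
#' confusion table at the 0.5 probability threshold, then adds Brier-style MSE
#' and AUC (AUC is `NA` with a flag when the fold holds a single class).
#'
#' @param labels 0/1 vector of ground truth.
#' @param prob predicted probability of class 1.
#' @return Named list: accuracy, precision, recall, f1, mcc, mse, auc,
#'   plus `auc_defined` flag.
#' @keywords internal
classification_report <- function(labels, prob) {
  labels <- as.integer(labels)
  pred <- as.integer(prob >= 0.5)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  cm <- suppressWarnings(confusion_metrics(tp, tn, fp, fn))
  auc_defined <- length(unique(labels)) == 2L
  auc <- if (auc_defined) roc_auc(labels, prob)$auc else NA_real_
  c(cm, list(mse = mse(labels, prob), auc = auc, auc_defined = auc_defined))
}
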