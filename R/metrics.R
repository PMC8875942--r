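# Confusion-matrix metrics and curve areas for link-prediction evaluation.

#' Threshold metrics from confusion counts
#'
#' Accuracy (TN+TP)/(TN+TP+FN+FP), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP) and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A metric whose
#' denominator is zero is reported as NaN with a warning.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return named numeric vector `Acc`, `Sen`, `Spec`, `Prec`, `MCC`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  acc  <- safe_div(tn + tp, tn + tp + fn + fp, "accuracy")
  sen  <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  mden <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mden == 0) {
    warning("MCC undefined: zero denominator")
    NaN
  } else (tp * tn - fp * fn) / mden
  c(Acc = acc, Sen = sen, Spec = spec, Prec = prec, MCC = mcc)
}

.check_binary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present")
  }
}

#' Area under the ROC curve
#'
#' Area under the FPR-vs-TPR curve over all score thresholds, computed as the
#' tie-corrected Mann-Whitney probability that a positive outscores a
#' negative (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return a single number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  .check_binary(scores, labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Precision and recall are evaluated at every distinct score threshold
#' (descending) and the curve, anchored at recall 0 with the first point's
#' precision, is integrated trapezoidally.
#'
#' @inheritParams roc_auc
#' @return a single number in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("at least one positive label required")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(1 - y)
  keep <- c(s[-1L] != s[-length(s)], TRUE)   # last index of each tie group
  tp <- cum_tp[keep]; fp <- cum_fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  rec0 <- c(0, rec)
  prec0 <- c(prec[1L], prec)
  sum(diff(rec0) * (prec0[-1L] + prec0[-length(prec0)]) / 2)
}
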