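# Validity assessment measures, computed per class (one-vs-rest) and
# macro-averaged:
#   accuracy    = (TP + TN) / (TP + TN + FP + FN)
#   PPV         = TP / (TP + FP)
#   NPV         = TN / (TN + FN)
#   sensitivity = TP / (TP + FN)
#   specificity = TN / (TN + FP)
#   MCC = (TP*TN - FP*FN) /
#         sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
# Degenerate denominators yield 0 (flagged), so trivial predictors do
# not crash. The report carries both the overall multi-class accuracy
# (trace of the 3x3 confusion table over N) and the per-class
# one-vs-rest accuracies: the two only coincide for binary problems.

#' One-vs-rest confusion counts per class
#'
#' @param truth,pred equal-length integer label vectors (values in
#'   `0..2` for the three-class problem; any common label set works).
#' @param classes label set (default: union of observed labels).
#' @return data.frame with one row per class: `class, TP, FP, TN, FN`.
#' @export
confusion_counts <- function(truth, pred, classes = sort(unique(c(truth, pred)))) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- length(truth) - tp - fn - fp
    data.frame(class = cl, TP = tp, FP = fp, TN = tn, FN = fn)
  }))
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Validity metrics from confusion counts
#'
#' @param cc data.frame from [confusion_counts()].
#' @return data.frame with per-class `accuracy, ppv, npv, sensitivity,
#'   specificity, mcc` plus a logical `degenerate` flag set when any
#'   denominator was zero.
#' @export
classification_metrics <- function(cc) {
  with(cc, {
    mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    data.frame(
      class = class,
      accuracy = (TP + TN) / (TP + TN + FP + FN),
      ppv = safe_div(TP, TP + FP),
      npv = safe_div(TN, TN + FN),
      sensitivity = safe_div(TP, TP + FN),
      specificity = safe_div(TN, TN + FP),
      mcc = safe_div(TP * TN - FP * FN, mcc_den),
      degenerate = (TP + FP) == 0 | (TN + FN) == 0 |
        (TP + FN) == 0 | (TN + FP) == 0)
  })
}

#' One-vs-rest ROC-AUC by the rank statistic
#'
#' AUC per class from the Mann-Whitney rank formula with mid-ranks for
#' ties (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param truth integer labels.
#' @param scores N x n_classes matrix of class scores (column j scores
#'   class `classes[j]`).
#' @param classes label set matching the score columns.
#' @return numeric vector of per-class AUCs.
#' @export
roc_auc <- function(truth, scores,
                    classes = sort(unique(truth))) {
  stopifnot(is.matrix(scores), nrow(scores) == length(truth),
            ncol(scores) == length(classes), all(is.finite(scores)))
  if (length(unique(truth)) < 2)
    stop("roc_auc() needs at least two classes in the truth labels")
  vapply(seq_along(classes), function(j) {
    pos <- truth == classes[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, j])                     # mid-ranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' ROC curve points for one class
#'
#' @param truth integer labels; `positive` is the positive class.
#' @param score numeric score for the positive class.
#' @param positive positive class label.
#' @return data.frame of (FPR, TPR) pairs over all score thresholds.
#' @export
roc_points <- function(truth, score, positive) {
  pos <- truth == positive
  ord <- order(score, decreasing = TRUE)
  tpr <- cumsum(pos[ord]) / sum(pos)
  fpr <- cumsum(!pos[ord]) / sum(!pos)
  data.frame(FPR = c(0, fpr), TPR = c(0, tpr))
}

#' Full metrics report
#'
#' @param truth,pred integer label vectors.
#' @param scores optional N x n_classes score matrix for AUC.
#' @return a `metrics_report`: list with `overall_accuracy` (trace of
#'   the multi-class confusion table over N), `per_class` (one-vs-rest
#'   accuracy/PPV/NPV/sensitivity/specificity/MCC/AUC) and `macro`
#'   (unweighted means over classes).
#' @export
metrics_report <- function(truth, pred, scores = NULL) {
  classes <- sort(unique(truth))
  cc <- confusion_counts(truth, pred, classes)
  per <- classification_metrics(cc)
  per$auc <- if (!is.null(scores)) roc_auc(truth, scores, classes)
  else NA_real_
  num <- per[, c("accuracy", "ppv", "npv", "sensitivity",
                 "specificity", "mcc", "auc")]
  structure(list(
    overall_accuracy = mean(truth == pred),
    confusion = cc,
    per_class = per,
    macro = colMeans(num)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  print(x$per_class, row.names = FALSE)
  cat("Macro:", paste(sprintf("%s=%.4f", names(x$macro), x$macro),
                      collapse = " "), "\n")
  invisible(x)
}
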