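#' Confusion counts from predicted and true labels
#'
#' The positive class is "abnormal" (+1).
#'
#' @param pred,truth label vectors in {-1, +1}.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  structure(list(
    TP = sum(pred > 0 & truth > 0), TN = sum(pred < 0 & truth < 0),
    FP = sum(pred > 0 & truth < 0), FN = sum(pred < 0 & truth > 0)
  ), class = "confusion_counts")
}

#' Classification metrics
#'
#' Accuracy, sensitivity, specificity and F1 from the confusion counts
#' (`Acc = (TP+TN)/(TP+TN+FP+FN)`, `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`), all reported as percentages; a metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.  AUC
#' is the area under the ROC curve of the positive-class scores, computed
#' with trapezoidal integration (equivalently the rank-sum statistic).
#'
#' @param counts a [confusion_counts()] (or list with TP/TN/FP/FN).
#' @param scores optional per-segment positive-class probabilities.
#' @param labels optional true labels in {-1, +1}, required with `scores`.
#' @return a `metrics_report` list with `Acc`, `Sen`, `Spe`, `F1`, `AUC`
#'   (percent; `AUC` is `NA` when scores are not supplied).
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop_invalid("counts must be >= 0")
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(labels)) stop_invalid("labels required with scores")
    if (length(unique(labels)) == 2) {
      roc <- pROC::roc(response = labels, predictor = scores,
                       levels = c(-1, 1), direction = "<", quiet = TRUE)
      auc <- 100 * as.numeric(pROC::auc(roc))
    }
  }
  structure(list(
    Acc = ratio(TP + TN, TP + TN + FP + FN),
    Sen = ratio(TP, TP + FN),
    Spe = ratio(TN, TN + FP),
    F1 = ratio(2 * TP, 2 * TP + FP + FN),
    AUC = auc
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Sen %.2f%%  Spe %.2f%%  F1 %.2f%%  AUC %s\n",
              x$Acc, x$Sen, x$Spe, x$F1,
              if (is.na(x$AUC)) "NA" else sprintf("%.2f%%", x$AUC)))
  invisible(x)
}
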