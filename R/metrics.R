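#' Confusion matrix for a binary classification
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param positive The positive class (e.g. `"malignant"`); defaults to the
#'   second sorted level of `truth`.
#' @return A `confusion_matrix` object with counts `tp`, `fp`, `tn`, `fn`
#'   and the positive class.
#' @export
confusion_matrix <- function(truth, pred, positive = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  if (length(truth) == 0L) stopf("cannot evaluate an empty test set")
  if (is.null(positive)) positive <- sort(unique(truth))[[length(unique(truth))]]
  structure(list(tp = sum(truth == positive & pred == positive),
                 fp = sum(truth != positive & pred == positive),
                 tn = sum(truth != positive & pred != positive),
                 fn = sum(truth == positive & pred != positive),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c(x$positive, "other"),
                              predicted = c(x$positive, "other")))
  print(m)
  invisible(x)
}

#' Confusion-matrix metric suite
#'
#' Computes the full evaluation panel in percent: accuracy
#' `(TP+TN)/total`, sensitivity `SE = TP/(TP+FN)`, specificity
#' `SP = TN/(TN+FP)`, precision `PRE = TP/(TP+FP)`, the complements
#' `FNR = 100 - SE` and `FPR = 100 - SP`, the F1 score
#' `2*PRE*SE/(PRE+SE)`, and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (reported both on
#' its natural `[-1, 1]` scale as `mcc` and in percent as `MCC`). If
#' classifier scores are supplied, AUC (percent) is added by trapezoidal
#' integration of the score-threshold ROC; with a single-class test set AUC
#' is undefined and reported as `NA`.
#'
#' @param cm A `confusion_matrix`, or the true labels (with `pred` given).
#' @param pred Predicted labels (when `cm` is the truth vector).
#' @param scores Optional numeric scores for the positive class (for AUC).
#' @param positive Positive class, see [confusion_matrix()].
#' @return A `metric_report`: named list `Acc`, `SE`, `SP`, `PRE`, `FNR`,
#'   `FPR`, `AUC`, `MCC`, `F1` (percent), `mcc` (raw), plus the confusion
#'   matrix.
#' @export
metric_report <- function(cm, pred = NULL, scores = NULL, positive = NULL) {
  truth <- NULL
  if (!inherits(cm, "confusion_matrix")) {
    truth <- cm
    cm <- confusion_matrix(truth, pred, positive = positive)
  }
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  se <- pct(tp, tp + fn); sp <- pct(tn, tn + fp); pre <- pct(tp, tp + fp)
  f1 <- if (!is.na(pre) && !is.na(se) && pre + se > 0) 2 * pre * se / (pre + se) else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  auc <- if (!is.null(scores) && !is.null(truth)) {
    if (length(unique(truth)) < 2L) NA_real_
    else 100 * roc_auc(roc_points(scores, truth, positive = cm$positive))
  } else NA_real_
  structure(list(Acc = pct(tp + tn, total), SE = se, SP = sp, PRE = pre,
                 FNR = if (is.na(se)) NA_real_ else 100 - se,
                 FPR = if (is.na(sp)) NA_real_ else 100 - sp,
                 AUC = auc, MCC = 100 * mcc, F1 = f1, mcc = mcc,
                 confusion = cm, n = total),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("Acc", "SE", "SP", "PRE", "FNR", "FPR", "AUC", "MCC", "F1")])
  print(round(v, digits))
  invisible(x)
}

#' ROC curve points from classifier scores
#'
#' Thresholds sweep the unique score values from high to low; each point is
#' the (FPR, TPR) of predicting positive at or above the threshold. The
#' curve starts at (0, 0) and ends at (1, 1); a constant score yields just
#' those two endpoints, so its trapezoidal AUC is 0.5.
#'
#' @param scores Numeric score for the positive class, higher = more
#'   positive.
#' @param truth True labels.
#' @param positive Positive class label.
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, truth, positive = NULL) {
  truth <- as.character(truth)
  if (is.null(positive)) positive <- sort(unique(truth))[[length(unique(truth))]]
  pos <- truth == positive
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stopf("ROC requires both classes in the test set")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nn, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' @rdname roc_points
#' @param roc Data frame from `roc_points()`.
#' @return `roc_auc`: area under the curve in `[0, 1]` by the trapezoid
#'   rule.
#' @export
roc_auc <- function(roc) {
  fpr <- c(roc$fpr, 1); tpr <- c(roc$tpr, 1)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
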