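# Evaluation suite for the binary granule-detection task.
#
# Positive = electron-dense granule present. The four outcomes of a
# prediction (TP, FN, FP, TN) are tabulated in a confusion matrix, from
# which derive
#   recall    = TP / (TP + FN)
#   precision = TP / (TP + FP)
#   F1        = 2 P R / (P + R)
#   accuracy  = (TP + TN) / N
#   FPR       = FP / (FP + TN),  TPR = TP / (TP + FN)
# The ROC curve sweeps all distinct score thresholds (predict Positive
# when score >= threshold) and AUROC is its trapezoidal area.

#' Confusion matrix from hard predictions
#'
#' @param y_true,y_pred equal-length 0/1 vectors (1 = Positive).
#' @return a `gn_confusion` list with integer counts `TP`, `FN`, `FP`,
#'   `TN`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred must have equal length")
  if (length(y_true) < 1L) stopf("empty evaluation set")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(y_true %in% 0:1) || !all(y_pred %in% 0:1))
    stopf("labels and predictions must be 0/1")
  new_confusion(TP = sum(y_true == 1L & y_pred == 1L),
                FN = sum(y_true == 1L & y_pred == 0L),
                FP = sum(y_true == 0L & y_pred == 1L),
                TN = sum(y_true == 0L & y_pred == 0L))
}

#' @rdname confusion_matrix
#' @param TP,FN,FP,TN nonnegative integer counts.
#' @export
new_confusion <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("confusion-matrix counts must be nonnegative integers")
  counts <- as.integer(counts)
  structure(list(TP = counts[1], FN = counts[2], FP = counts[3],
                 TN = counts[4]), class = "gn_confusion")
}

#' @export
print.gn_confusion <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2L, 2L, byrow = TRUE,
              dimnames = list(`Ground truth` = c("Positive", "Negative"),
                              Prediction = c("Positive", "Negative")))
  print(m)
  invisible(x)
}

#' Recall (sensitivity): TP / (TP + FN)
#' @param cm a `gn_confusion`.
#' @return value in `[0, 1]`; errors when no positive instances exist.
#' @export
recall <- function(cm) {
  if (cm$TP + cm$FN == 0L) stopf("recall undefined: no positive instances")
  cm$TP / (cm$TP + cm$FN)
}

#' Precision: TP / (TP + FP)
#' @param cm a `gn_confusion`.
#' @return value in `[0, 1]`; errors when nothing was predicted positive.
#' @export
precision <- function(cm) {
  if (cm$TP + cm$FP == 0L) stopf("precision undefined: no positive predictions")
  cm$TP / (cm$TP + cm$FP)
}

#' F1 score: harmonic mean of precision and recall
#' @param p,r precision and recall values, or a single `gn_confusion` as
#'   `p`.
#' @return value in `[0, 1]`.
#' @export
f1_score <- function(p, r = NULL) {
  if (inherits(p, "gn_confusion")) { r <- recall(p); p <- precision(p) }
  if (p + r == 0) stopf("F1 undefined: precision + recall = 0")
  2 * p * r / (p + r)
}

#' Accuracy: (TP + TN) / N
#' @param cm a `gn_confusion`.
#' @return value in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  n <- cm$TP + cm$FN + cm$FP + cm$TN
  if (n == 0L) stopf("accuracy undefined: empty confusion matrix")
  (cm$TP + cm$TN) / n
}

#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold (prediction Positive when
#' `score >= threshold`; tied scores share one threshold point), computes
#' (FPR, TPR) per threshold, prepends (0, 0) and appends (1, 1), and
#' integrates trapezoidally.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores finite numeric scores, higher = more positive.
#' @return a `gn_roc` list: `points` (data frame `fpr`, `tpr`,
#'   `threshold`) and `auroc`.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stopf("y_true/scores length mismatch")
  assert_finite(scores, "scores")
  P <- sum(y_true == 1L); N <- sum(y_true == 0L)
  if (P == 0L || N == 0L)
    stopf("ROC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]; ss <- scores[ord]
  tp <- cumsum(ys == 1L); fp <- cumsum(ys == 0L)
  last <- !duplicated(ss, fromLast = TRUE)   # one point per distinct score
  pts <- data.frame(fpr = c(0, fp[last] / N, 1),
                    tpr = c(0, tp[last] / P, 1),
                    threshold = c(Inf, ss[last], -Inf))
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), ]
  au <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auroc = au), class = "gn_roc")
}

#' @rdname roc_curve
#' @export
auroc <- function(y_true, scores) roc_curve(y_true, scores)$auroc

#' Full metric report for one model
#'
#' @param y_true 0/1 labels.
#' @param scores continuous scores in any monotone scale.
#' @param threshold hard-label cutoff on `scores` (default 0.5, suited to
#'   probability-scale scores).
#' @return list with the confusion matrix, raw metrics, 2-dp rounded
#'   metrics (report print precision), and the ROC curve.
#' @export
evaluate_model <- function(y_true, scores, threshold = 0.5) {
  cm <- confusion_matrix(y_true, as.integer(scores >= threshold))
  roc <- roc_curve(y_true, scores)
  raw <- c(precision = precision(cm), recall = recall(cm),
           f1 = f1_score(cm), accuracy = accuracy(cm), auroc = roc$auroc)
  list(confusion = cm, metrics = raw, metrics_2dp = round(raw, 2L),
       roc = roc)
}

#' Write a multi-model ROC comparison plot
#'
#' Draws each model's ROC curve with the diagonal random-guessing
#' reference line and AUROC values in the legend.
#'
#' @param rocs named list of `gn_roc` objects.
#' @param path output PNG path.
#' @return invisibly, `path`.
#' @export
plot_roc <- function(rocs, path) {
  grDevices::png(path, width = 720, height = 720, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "ROC curves")
  graphics::abline(0, 1, lty = 2, col = "grey50")
  cols <- grDevices::hcl.colors(max(3L, length(rocs)), "Dark 3")
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$points$fpr, rocs[[i]]$points$tpr,
                    col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUROC = %.3f)", names(rocs),
                                    vapply(rocs, `[[`, 0, "auroc")),
                   col = cols[seq_along(rocs)], lwd = 2, bty = "n")
  invisible(path)
}
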