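## ROC/AUC, confusion counts, F1 and evaluation reports.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values, grouping
#' tied scores into a single step, and accumulates (FPR, TPR) points from
#' (0, 0) to (1, 1).  AUC is the trapezoidal area under those points,
#' which is equivalent to the Mann-Whitney pairwise statistic with ties
#' given half credit.  Precision-recall points come from the same sweep.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels 0/1 labels (or a logical vector).
#' @return List with `auc`, `roc_points` (data.frame `fpr`, `tpr`) and
#'   `pr_points` (data.frame `recall`, `precision`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("AUC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # one step per distinct score value
  last_of_group <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1L - y)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  precision <- c(1, tp / (tp + fp))
  recall <- tpr
  list(auc = auc,
       roc_points = data.frame(fpr = fpr, tpr = tpr),
       pr_points = data.frame(recall = recall, precision = precision))
}

#' Confusion counts at a threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `confusion_counts`: list with `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 FP = sum(pred == 1L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L),
                 TN = sum(pred == 0L & labels == 0L)),
            class = "confusion_counts")
}

#' F1 score from confusion counts
#'
#' F1 = 2TP / (2TP + FN + FP), the harmonic mean of precision and recall.
#' When the denominator is zero (no true positives and no errors of
#' either kind) the score is defined as 0, with a warning.
#'
#' @param confusion A [confusion_counts()] object, or a list with
#'   elements `TP`, `FP`, `FN`.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(confusion) {
  tp <- confusion$TP; fp <- confusion$FP; fn <- confusion$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  den <- 2 * tp + fn + fp
  if (den == 0) {
    warning("F1 undefined (2TP + FN + FP = 0); returning 0")
    return(0)
  }
  2 * tp / den
}

#' Evaluate a fitted model on held-out pairs
#'
#' @param model A [tune_and_train()] model.
#' @param test_features Feature table (or matrix) with the training
#'   columns.
#' @param test_labels 0/1 labels aligned with the rows.
#' @param threshold Threshold for the confusion matrix and F1
#'   (default 0.5).
#' @return An object of class `evaluation_report`: list with `auc`, `f1`,
#'   `threshold`, `roc_points`, `pr_points`, `confusion`, `n`.
#' @export
evaluate <- function(model, test_features, test_labels, threshold = 0.5) {
  scores <- predict_scores(model, test_features)
  r <- roc_auc(scores, test_labels)
  cc <- confusion_counts(scores, test_labels, threshold)
  structure(list(auc = r$auc, f1 = f1_score(cc), threshold = threshold,
                 roc_points = r$roc_points, pr_points = r$pr_points,
                 confusion = cc, n = length(scores)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d pairs: AUC = %.4f, F1 = %.4f (threshold %.2f)\n",
              x$n, x$auc, x$f1, x$threshold))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n",
              x$confusion$TP, x$confusion$FP, x$confusion$FN, x$confusion$TN))
  invisible(x)
}
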