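#' Confusion matrix for two-class predictions
#'
#' @param predicted,truth Character/factor vectors of equal length with
#'   values in the two-class outcome set.
#' @return A 2x2 integer matrix `n[true, predicted]` with class
#'   `raman_confusion` (rows: true class, columns: predicted class, order
#'   pregnancy then non-pregnancy).
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth) || !length(truth)) {
    stop("predicted and truth must have equal positive length")
  }
  check_label(predicted); check_label(truth)
  pf <- factor(as.character(predicted), levels = outcome_levels())
  tf <- factor(as.character(truth), levels = outcome_levels())
  if (anyNA(pf) || anyNA(tf)) stop("NA labels in predictions or truth")
  cm <- table(true = tf, predicted = pf)
  structure(unclass(cm), class = c("raman_confusion", "matrix"))
}

#' @export
print.raman_confusion <- function(x, ...) {
  cat("Confusion matrix (rows: true, columns: predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Per class: precision (column-wise), recall (row-wise), their harmonic
#' mean F1, and the per-class accuracy -- the class recall expressed as a
#' percent, which is how per-class "accuracy" is commonly tabulated
#' alongside the overall trace/total accuracy. Metrics with a zero
#' denominator are reported as `NA`.
#'
#' @param cm A [confusion()] matrix (or any 2x2 matrix `n[true, predicted]`
#'   with classes in the order pregnancy, non-pregnancy).
#' @return Object of class `eval_report`: `per_class` data frame
#'   (`precision`, `recall`, `f1`, `accuracy_pct`), `overall_accuracy`,
#'   `correct`, `total`.
#' @export
#' @examples
#' cm <- matrix(c(31, 13, 14, 37), 2,
#'              dimnames = list(true = c("pregnancy", "non_pregnancy"),
#'                              predicted = c("pregnancy", "non_pregnancy")))
#' eval_metrics(cm)
eval_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == 2, ncol(cm) == 2, all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  lev <- outcome_levels()
  prec <- rec <- f1 <- numeric(2)
  for (c in 1:2) {
    pc <- sum(cm[, c]); tc <- sum(cm[c, ])
    prec[c] <- if (pc > 0) cm[c, c] / pc else NA_real_
    rec[c] <- if (tc > 0) cm[c, c] / tc else NA_real_
    f1[c] <- if (!is.na(prec[c]) && !is.na(rec[c]) && prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else NA_real_
  }
  correct <- sum(diag(cm))
  structure(list(
    per_class = data.frame(class = lev, precision = prec, recall = rec,
                           f1 = f1, accuracy_pct = 100 * rec,
                           stringsAsFactors = FALSE),
    overall_accuracy = correct / total,
    correct = correct, total = total, confusion = cm),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Performance evaluation\n")
  pc <- x$per_class
  pc$precision <- round(pc$precision, 2)
  pc$recall <- round(pc$recall, 2)
  pc$f1 <- round(pc$f1, 2)
  pc$accuracy_pct <- round(pc$accuracy_pct, 2)
  print(pc, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.2f%% (%d/%d)\n",
              100 * x$overall_accuracy, x$correct, x$total))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (score >= threshold predicts
#' the positive class), accumulating the true- and false-positive rates, and
#' integrates the curve by the trapezoid rule. Tied scores advance the curve
#' diagonally, so the trapezoid area equals the Mann-Whitney statistic with
#' half-credit for ties; the AUC is therefore invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores Numeric score for the positive class, one per observation.
#' @param truth Outcome labels.
#' @param positive Positive class (default `"pregnancy"`).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "pregnancy") {
  truth <- as.character(truth)
  check_label(truth)
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("undefined AUC: both classes must be present in truth")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  # cumulative counts at each unique threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  roc <- data.frame(threshold = c(Inf, s[last_of_tie]),
                    fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}
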