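# Classification metrics: confusion matrices, accuracy / precision /
# recall / F1 (reported as percentages, two decimals in printed output),
# macro averaging, and rank-based AUC. Class labels are 0-based integers
# throughout the package.

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i - 1` predicted as class
#' `j - 1`.
#'
#' @param y_true,y_pred Integer label vectors in `[0, K)`, equal length.
#' @param K Number of classes (default: inferred from the labels).
#' @return `K x K` integer matrix with class labels as dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, K = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) == 0) stop("empty label vectors")
  if (is.null(K)) K <- max(y_true, y_pred) + 1L
  if (any(y_true < 0 | y_true >= K) || any(y_pred < 0 | y_pred >= K)) {
    stop("labels must lie in [0, ", K, ")")
  }
  cm <- table(factor(y_true, levels = 0:(K - 1)),
              factor(y_pred, levels = 0:(K - 1)))
  m <- matrix(as.integer(cm), nrow = K,
              dimnames = list(true = 0:(K - 1), predicted = 0:(K - 1)))
  m
}

#' Per-class TP/FP/FN/TN counts
#'
#' One-vs-rest decomposition of a confusion matrix; for every class
#' `TP + TN + FP + FN` equals the total sample count.
#'
#' @param cm Square confusion matrix (true classes in rows).
#' @return Data frame with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  data.frame(class = seq_len(nrow(cm)) - 1L,
             tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), tn = as.integer(tn))
}

#' Overall accuracy (percent)
#'
#' `(TP + TN) / total` for binary tasks, equivalently the trace of the
#' confusion matrix over the grand total for any number of classes.
#'
#' @param cm Confusion matrix.
#' @return Accuracy as a percentage.
#' @examples
#' accuracy(matrix(c(149, 0, 1, 150), 2)) # 99.67 (2 d.p.)
#' @export
accuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

zero_safe_ratio <- function(num, den) {
  out <- ifelse(den == 0, 0, num / den)
  attr(out, "undefined") <- which(den == 0) - 1L
  out
}

#' Per-class precision (percent)
#'
#' `TP / (TP + FP)` per class; classes with a zero denominator are reported
#' as 0 and flagged in the `"undefined"` attribute so macro means stay
#' total.
#'
#' @param cm Confusion matrix.
#' @return Numeric vector of per-class percentages.
#' @export
precision_by_class <- function(cm) {
  cc <- confusion_counts(cm)
  100 * zero_safe_ratio(cc$tp, cc$tp + cc$fp)
}

#' Per-class recall (percent)
#'
#' `TP / (TP + FN)` per class, with the same zero-denominator convention as
#' [precision_by_class()].
#'
#' @param cm Confusion matrix.
#' @return Numeric vector of per-class percentages.
#' @export
recall_by_class <- function(cm) {
  cc <- confusion_counts(cm)
  100 * zero_safe_ratio(cc$tp, cc$tp + cc$fn)
}

#' Per-class F1 score (percent)
#'
#' Harmonic mean of per-class precision and recall; 0 when both are 0.
#'
#' @param cm Confusion matrix.
#' @return Numeric vector of per-class percentages.
#' @export
f1_by_class <- function(cm) {
  p <- precision_by_class(cm)
  r <- recall_by_class(cm)
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Macro average
#'
#' Unweighted mean of per-class metric values.
#'
#' @param values Per-class values.
#' @return Scalar mean.
#' @export
macro_average <- function(values) mean(values)

auc_binary <- function(pos, scores) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores) # midranks on ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank-based AUC
#'
#' Binary: the Mann-Whitney statistic of the positive-class scores, with
#' midranks on ties (equivalent to counting concordant positive-negative
#' pairs, ties at 1/2). Multiclass: one-vs-rest macro average over the
#' score columns.
#'
#' @param y_true Integer labels in `[0, K)`.
#' @param scores For binary input, a vector of positive-class scores or a
#'   two-column probability matrix; for multiclass, an `n x K` probability
#'   matrix.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)) # 0.75
#' @export
auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2) {
    stop("AUC undefined: y_true contains a single class")
  }
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    if (ncol(scores) == 2) return(auc_binary(y_true == 1, scores[, 2]))
    per_class <- vapply(seq_len(ncol(scores)), function(k) {
      cls <- k - 1L
      if (!any(y_true == cls)) return(NA_real_)
      auc_binary(y_true == cls, scores[, k])
    }, numeric(1))
    return(mean(per_class, na.rm = TRUE))
  }
  auc_binary(y_true == 1, scores)
}

#' Full metric report
#'
#' Computes the confusion matrix, accuracy, macro (or support-weighted)
#' precision / recall / F1, per-class values, and AUC when probabilities
#' are supplied. All rates are percentages; AUC is on `[0, 1]`.
#'
#' @param y_true,y_pred Integer label vectors in `[0, K)`.
#' @param probs Optional `n x K` probability matrix for AUC.
#' @param K Number of classes (default inferred).
#' @param average `"macro"` (default) or `"weighted"` by class support.
#' @return An object of class `metric_report` (a list), convertible to JSON.
#' @export
metric_report <- function(y_true, y_pred, probs = NULL, K = NULL,
                          average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- confusion_matrix(y_true, y_pred, K)
  p <- precision_by_class(cm)
  r <- recall_by_class(cm)
  f <- f1_by_class(cm)
  w <- if (average == "macro") rep(1 / nrow(cm), nrow(cm))
       else rowSums(cm) / sum(cm)
  auc_val <- if (!is.null(probs)) auc(y_true, probs) else NA_real_
  structure(
    list(accuracy = accuracy(cm),
         precision = sum(w * p), recall = sum(w * r), f1 = sum(w * f),
         auc = auc_val,
         average = average,
         per_class = data.frame(class = seq_len(nrow(cm)) - 1L,
                                precision = as.numeric(p),
                                recall = as.numeric(r),
                                f1 = as.numeric(f)),
         confusion = unname(cm)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> accuracy %.2f%% | %s precision %.2f%% recall %.2f%% f1 %.2f%%",
              x$accuracy, x$average, x$precision, x$recall, x$f1))
  if (!is.na(x$auc)) cat(sprintf(" | AUC %.3f", x$auc))
  cat("\n")
  invisible(x)
}
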