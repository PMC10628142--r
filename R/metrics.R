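#' Confusion matrix from true and predicted labels
#'
#' Accumulates (true, predicted) label pairs into a K x K count matrix, rows
#' indexing the true class and columns the predicted class. All four
#' evaluation measures (accuracy, precision, recall, F1) derive from these
#' counts via per-class one-vs-rest true/false positives and negatives.
#'
#' @param true,predicted Integer labels in `1..length(class_names)`.
#' @param class_names Character vector of the K class labels, K >= 2.
#' @return An object of class `fl_confusion`: integer K x K matrix with
#'   dimnames `(true, predicted)`.
#' @export
confusion_matrix <- function(true, predicted, class_names) {
  class_names <- as.character(class_names)
  K <- length(class_names)
  if (K < 2L) .fl_stop("at least 2 classes are required")
  true <- as.integer(true); predicted <- as.integer(predicted)
  if (length(true) != length(predicted)) {
    .fl_stop("`true` and `predicted` must have the same length")
  }
  for (v in list(true, predicted)) {
    if (length(v) && (anyNA(v) || min(v) < 1L || max(v) > K)) {
      .fl_stop(sprintf("labels must lie in 1..%d", K))
    }
  }
  counts <- matrix(0L, K, K, dimnames = list(true = class_names,
                                             predicted = class_names))
  for (i in seq_along(true)) {
    counts[true[i], predicted[i]] <- counts[true[i], predicted[i]] + 1L
  }
  structure(counts, class = c("fl_confusion", "matrix", "array"))
}

.check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2L) {
    .fl_stop("`cm` must be a square K x K matrix with K >= 2")
  }
  if (any(cm < 0)) .fl_stop("confusion matrix counts must be non-negative")
  if (sum(cm) == 0) .fl_stop("confusion matrix is empty (total count 0)")
  invisible(cm)
}

#' Overall accuracy of a confusion matrix
#'
#' Proportion of correct predictions among all predictions. In the binary
#' one-vs-rest view this is `(TP + TN) / (TP + FP + TN + FN)`; for a K-class
#' matrix it equals `trace / total`, which coincides with that formula when
#' K = 2.
#'
#' @param cm A K x K confusion matrix (rows true, columns predicted).
#' @return A number in `[0, 1]`.
#' @export
cm_accuracy <- function(cm) {
  .check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

# per-class one-vs-rest counts: TP, FP, FN (TN is the remainder)
.per_class_counts <- function(cm) {
  tp <- diag(cm)
  list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp)
}

.safe_ratio <- function(num, den, what, average) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0) && average == "macro") {
    warning(sprintf("%s undefined for %d class(es) (zero denominator); counted as 0",
                    what, sum(den == 0)), call. = FALSE)
  }
  out
}

#' Precision of a confusion matrix
#'
#' Per class (one-vs-rest), `Precision = TP / (TP + FP)`: the model's ability
#' not to label a negative sample as positive. `"macro"` averaging (default)
#' takes the unweighted mean over classes, with a class that was never
#' predicted contributing 0 under a warning; `"micro"` pools the counts over
#' classes first.
#'
#' @inheritParams cm_accuracy
#' @param average `"macro"` or `"micro"`.
#' @return A number in `[0, 1]`.
#' @export
cm_precision <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  .check_cm(cm)
  ct <- .per_class_counts(cm)
  if (average == "micro") {
    return(sum(ct$tp) / (sum(ct$tp) + sum(ct$fp)))
  }
  mean(.safe_ratio(ct$tp, ct$tp + ct$fp, "precision", average))
}

#' Recall of a confusion matrix
#'
#' Per class (one-vs-rest), `Recall = TP / (TP + FN)`: the model's ability to
#' find all positive samples. Averaging as in [cm_precision()]; a class with
#' no true instances contributes 0 under a warning.
#'
#' @inheritParams cm_precision
#' @return A number in `[0, 1]`.
#' @export
cm_recall <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  .check_cm(cm)
  ct <- .per_class_counts(cm)
  if (average == "micro") {
    return(sum(ct$tp) / (sum(ct$tp) + sum(ct$fn)))
  }
  mean(.safe_ratio(ct$tp, ct$tp + ct$fn, "recall", average))
}

#' F1 score of a confusion matrix
#'
#' Per class, the harmonic mean
#' `F1 = 2 * Precision * Recall / (Precision + Recall)`, with a class whose
#' precision and recall are both 0 contributing 0. `"macro"` averages the
#' per-class F1 values; `"micro"` computes the harmonic mean of the pooled
#' precision and recall.
#'
#' @inheritParams cm_precision
#' @return A number in `[0, 1]`.
#' @export
cm_f1 <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  .check_cm(cm)
  ct <- .per_class_counts(cm)
  if (average == "micro") {
    p <- sum(ct$tp) / (sum(ct$tp) + sum(ct$fp))
    r <- sum(ct$tp) / (sum(ct$tp) + sum(ct$fn))
    return(if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  p <- ifelse(ct$tp + ct$fp > 0, ct$tp / (ct$tp + ct$fp), 0)
  r <- ifelse(ct$tp + ct$fn > 0, ct$tp / (ct$tp + ct$fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  mean(f1)
}

#' All four evaluation measures of a confusion matrix
#'
#' @inheritParams cm_precision
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
cm_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  c(accuracy = cm_accuracy(cm),
    precision = suppressWarnings(cm_precision(cm, average)),
    recall = suppressWarnings(cm_recall(cm, average)),
    f1 = suppressWarnings(cm_f1(cm, average)))
}

#' Write a confusion matrix as labeled CSV
#'
#' @param cm An `fl_confusion` matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_confusion_csv <- function(cm, path) {
  .check_cm(cm)
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
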