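# Confusion-matrix evaluation: per-class precision, recall and specificity
# (one-vs-rest) plus mean accuracy. Cells with zero denominators are
# reported as NA, never as zero.

#' Confusion matrix
#'
#' @param true_labels,predicted_labels integer class labels in `1:K` (or
#'   factors with identical levels).
#' @param K number of classes; inferred from the data when omitted.
#' @return `K x K` integer matrix; rows are true classes, columns predicted.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, K = NULL) {
  if (is.factor(true_labels)) true_labels <- as.integer(true_labels)
  if (is.factor(predicted_labels)) predicted_labels <- as.integer(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(true_labels), length(predicted_labels)))
  }
  if (is.null(K)) K <- max(true_labels, predicted_labels)
  if (any(true_labels < 1L | true_labels > K) ||
      any(predicted_labels < 1L | predicted_labels > K)) {
    stop("labels must lie in 1..K")
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(true_labels)) {
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  }
  cm
}

#' Per-class metrics from a confusion matrix
#'
#' For each class (one-vs-rest): precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`; mean accuracy is
#' `trace/total`. Undefined cells (zero denominator) are `NA`.
#'
#' @param cm a square confusion matrix (rows = true classes).
#' @param class_names optional class names for the report.
#' @return An object of class `eval_report`: list with `confusion`,
#'   `metrics` (data frame: class, precision, recall, specificity) and
#'   `accuracy`.
#' @export
per_class_metrics <- function(cm, class_names = NULL) {
  K <- nrow(cm)
  if (ncol(cm) != K) stop("confusion matrix must be square")
  total <- sum(cm)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- rec <- spec <- numeric(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    prec[c] <- safe_div(tp, tp + fp)
    rec[c] <- safe_div(tp, tp + fn)
    spec[c] <- safe_div(tn, tn + fp)
  }
  structure(list(
    confusion = cm,
    metrics = data.frame(class = class_names, precision = prec,
                         recall = rec, specificity = spec,
                         stringsAsFactors = FALSE),
    accuracy = if (total == 0) NA_real_ else sum(diag(cm)) / total),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  cat("\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat(sprintf("\nMean accuracy: %.4f\n", x$accuracy))
  invisible(x)
}
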