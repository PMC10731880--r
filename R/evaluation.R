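#' Build a confusion matrix from prediction and gold label vectors
#'
#' Rows are predicted labels, columns are gold-standard labels, following the
#' layout of published CHEMPROT confusion matrices.
#'
#' @param predictions character vector of predicted labels.
#' @param golds character vector of gold labels, same length.
#' @param labels ordered character vector covering every label that may occur.
#' @return an integer matrix of class `gpnre_confusion` with `dimnames`
#'   `list(predicted = labels, gold = labels)`.
#' @export
confusion_matrix <- function(predictions, golds, labels) {
  if (length(predictions) != length(golds)) {
    stop("predictions and golds must have equal length")
  }
  unknown <- setdiff(unique(c(predictions, golds)), labels)
  if (length(unknown) > 0) {
    stop("labels not in label set: ", paste(unknown, collapse = ", "))
  }
  p <- factor(predictions, levels = labels)
  g <- factor(golds, levels = labels)
  counts <- table(predicted = p, gold = g)
  m <- matrix(as.integer(counts), nrow = length(labels),
              dimnames = list(predicted = labels, gold = labels))
  class(m) <- c("gpnre_confusion", class(m))
  m
}

#' Micro-averaged precision, recall and F1 over the positive classes
#'
#' True positives for a positive class are its diagonal cell; false positives
#' are the off-diagonal cells of its row (instances predicted as that class
#' with a different gold label); false negatives the off-diagonal cells of its
#' column. The sums run over the positive classes only: the catch-all negative
#' label contributes to FP/FN but its own cell is never a TP, which is the
#' convention under which the published CHEMPROT matrices reproduce their
#' printed micro scores.
#'
#' @param matrix confusion matrix (rows predicted, columns gold) with label
#'   dimnames.
#' @param positive_labels labels treated as positive classes.
#' @return named numeric vector `c(precision, recall, f1)` in percent, rounded
#'   to 2 decimals.
#' @export
micro_metrics <- function(matrix, positive_labels) {
  labels <- rownames(matrix)
  if (!all(positive_labels %in% labels)) {
    stop("positive_labels must be a subset of the matrix labels")
  }
  tp <- fp <- fn <- 0
  for (lab in positive_labels) {
    i <- match(lab, labels)
    tp <- tp + matrix[i, i]
    fp <- fp + sum(matrix[i, -i])
    fn <- fn + sum(matrix[-i, i])
  }
  p <- .safe_ratio(tp, tp + fp, "micro precision")
  r <- .safe_ratio(tp, tp + fn, "micro recall")
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  round(c(precision = p, recall = r, f1 = f) * 100, 2)
}

#' Per-class one-vs-rest precision, recall and F1
#'
#' @param matrix confusion matrix (rows predicted, columns gold).
#' @return data frame with one row per label and percent-scale columns
#'   `precision`, `recall`, `f1` rounded to 2 decimals.
#' @export
per_class_metrics <- function(matrix) {
  labels <- rownames(matrix)
  out <- data.frame(label = labels, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    tp <- matrix[i, i]
    p <- .safe_ratio(tp, sum(matrix[i, ]), paste("precision of", labels[i]))
    r <- .safe_ratio(tp, sum(matrix[, i]), paste("recall of", labels[i]))
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    out$precision[i] <- round(p * 100, 2)
    out$recall[i] <- round(r * 100, 2)
    out$f1[i] <- round(f * 100, 2)
  }
  out
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator for ", what, "; reporting 0")
    return(0)
  }
  num / den
}

#' Full evaluation report from predictions or a confusion matrix
#'
#' @param predictions,golds label vectors (ignored when `matrix` is given).
#' @param matrix optional pre-tallied confusion matrix.
#' @param scheme a [label_scheme()]; its evaluated labels are the positive
#'   classes of the micro average.
#' @return object of class `gpnre_eval` with elements `micro`, `per_class`,
#'   `matrix`.
#' @export
eval_report <- function(predictions = NULL, golds = NULL, matrix = NULL,
                        scheme = chemprot_scheme()) {
  labels <- c(scheme$negative_label, scheme$evaluated_labels)
  if (is.null(matrix)) {
    matrix <- confusion_matrix(predictions, golds, labels)
  } else {
    if (is.null(rownames(matrix))) {
      stop("matrix must carry label dimnames")
    }
  }
  rep <- list(micro = micro_metrics(matrix, scheme$evaluated_labels),
              per_class = per_class_metrics(matrix),
              matrix = matrix)
  class(rep) <- "gpnre_eval"
  rep
}

#' @export
print.gpnre_eval <- function(x, ...) {
  cat("Relation-extraction evaluation\n")
  cat(sprintf("  micro: precision %.2f%%  recall %.2f%%  F1 %.2f%%\n",
              x$micro["precision"], x$micro["recall"], x$micro["f1"]))
  cat("  per class:\n")
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("    %-8s P %6.2f  R %6.2f  F1 %6.2f\n",
                pc$label[i], pc$precision[i], pc$recall[i], pc$f1[i]))
  }
  invisible(x)
}

#' Read / write a confusion matrix as TSV
#'
#' The TSV carries a header row of gold labels and a leading column of
#' predicted labels, so a printed matrix can be typed in directly and
#' evaluated without any model run.
#'
#' @param path file path.
#' @return for `read_confusion_tsv`, a labelled integer matrix.
#' @export
read_confusion_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), labels)) {
    stop("row labels and column header disagree: ",
         paste(labels, collapse = ","), " vs ",
         paste(colnames(m), collapse = ","))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(predicted = labels, gold = labels)
  class(m) <- c("gpnre_confusion", class(m))
  m
}

#' @rdname read_confusion_tsv
#' @param matrix labelled confusion matrix to write.
#' @export
write_confusion_tsv <- function(matrix, path) {
  df <- data.frame(label = rownames(matrix), unclass(matrix)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
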