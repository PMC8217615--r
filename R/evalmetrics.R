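#' Confusion matrix of a binary classifier
#'
#' Tallies every (label, prediction) pair over classes `{0, 1}`.
#'
#' @param preds integer predictions in `{0, 1}`.
#' @param labels integer ground-truth labels in `{0, 1}`, same length.
#' @return object of class `confusion_matrix`: a 2x2 integer matrix with
#'   rows = actual class, columns = predicted class.
#' @export
confusion <- function(preds, labels) {
  if (length(preds) != length(labels))
    stop("preds and labels must have the same length")
  if (!all(preds %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("class ids must be 0 or 1")
  m <- matrix(0L, 2, 2,
              dimnames = list(actual = c("0", "1"), predicted = c("0", "1")))
  for (a in 0:1) for (p in 0:1)
    m[a + 1, p + 1] <- sum(labels == a & preds == p)
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Build a confusion matrix directly from correct/total counts
#'
#' Convenience constructor for published results reported as "x of n images
#' correctly classified" per class: misclassified items of one class are
#' counted as predictions of the other (binary setting).
#'
#' @param correct0,n0 correct and total counts for class 0.
#' @param correct1,n1 correct and total counts for class 1.
#' @return a `confusion_matrix`.
#' @export
confusion_from_counts <- function(correct0, n0, correct1, n1) {
  if (correct0 > n0 || correct1 > n1 || min(correct0, correct1) < 0)
    stop("correct counts must lie in [0, n]")
  m <- matrix(as.integer(c(correct0, n0 - correct0,
                           n1 - correct1, correct1)), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("0", "1"), predicted = c("0", "1")))
  structure(m, class = c("confusion_matrix", "matrix"))
}

cm_counts <- function(cm, positive) {
  i <- positive + 1L; j <- 2L - positive
  list(tp = cm[i, i], fp = cm[j, i], fn = cm[i, j], tn = cm[j, j])
}

#' Precision, recall and F1 for one positive class
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. F1 is 1 when there
#' is neither FP nor FN and 0 when there is no TP; empty denominators give
#' 0 (a precision of 0 with no predicted positives, a recall of 0 with no
#' actual positives).
#'
#' @param cm a [confusion()] matrix.
#' @param positive the class id treated as positive (0 or 1).
#' @return named numeric `c(precision, recall, f1)`, in percent.
#' @export
precision_recall_f1 <- function(cm, positive = 0L) {
  stopifnot(inherits(cm, "confusion_matrix"), positive %in% c(0, 1))
  k <- cm_counts(cm, as.integer(positive))
  p <- if (k$tp + k$fp == 0) 0 else k$tp / (k$tp + k$fp)
  r <- if (k$tp + k$fn == 0) 0 else k$tp / (k$tp + k$fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f1 = 100 * f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`, with 0 when both are 0. Accepts percentages
#' and returns the same scale.
#'
#' @param precision,recall values in `[0,100]` (or `[0,1]`; the scale is
#'   preserved).
#' @return F1 on the input scale.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm a [confusion()] matrix.
#' @return accuracy in percent (correct / total * 100).
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  100 * sum(diag(cm)) / total
}

#' Full metrics report
#'
#' Per-class precision/recall/F1 (each class taken as positive in turn)
#' plus overall accuracy, formatted to four decimal places (half-even
#' rounding) the way such results are conventionally tabulated.
#'
#' @param cm a [confusion()] matrix.
#' @param class_names length-2 character names for classes 0 and 1.
#' @return object of class `metrics_report`: list with `table` (data.frame
#'   `class, precision, recall, f1`), `accuracy`, and `confusion`.
#' @export
metrics_report <- function(cm, class_names = c("longitudinal_division",
                                               "other_division")) {
  rows <- lapply(0:1, function(k) {
    m <- precision_recall_f1(cm, k)
    data.frame(class = class_names[k + 1], precision = m[["precision"]],
               recall = m[["recall"]], f1 = m[["f1"]])
  })
  structure(list(table = do.call(rbind, rows), accuracy = accuracy(cm),
                 confusion = cm),
            class = "metrics_report")
}

fmt_pct <- function(x) sprintf("%.4f%%", round(x, 4))

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(unclass(x$confusion))
  cat(sprintf("\nOverall accuracy: %s\n\n", fmt_pct(x$accuracy)))
  tab <- x$table
  tab$precision <- fmt_pct(tab$precision)
  tab$recall <- fmt_pct(tab$recall)
  tab$f1 <- fmt_pct(tab$f1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' Writes `confusion.csv` (the 2x2 counts) and `metrics.csv` (per-class
#' precision/recall/F1 rows plus an overall-accuracy row) under `dir`.
#'
#' @param report a [metrics_report()].
#' @param dir output directory.
#' @return invisibly, the two file paths.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cpath <- file.path(dir, "confusion.csv")
  mpath <- file.path(dir, "metrics.csv")
  write.csv(as.data.frame(unclass(report$confusion)), cpath)
  tab <- report$table
  tab <- rbind(tab, data.frame(class = "overall_accuracy",
                               precision = NA, recall = NA,
                               f1 = report$accuracy))
  write.csv(tab, mpath, row.names = FALSE)
  invisible(c(cpath, mpath))
}
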