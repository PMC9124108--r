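#' Build a 2x2 confusion matrix
#'
#' Tallies (actual, predicted) pairs of binary labels into a 2x2 table with
#' actual classes in rows and predicted classes in columns.
#'
#' @param y_true,y_pred equal-length vectors of 0/1 labels.
#' @return A `"confusion2x2"`: an integer matrix with dimnames
#'   `actual` x `predicted`.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1))
confusion_matrix <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop_invalid("label vectors are empty")
  if (length(y_true) != length(y_pred))
    stop_invalid("y_true and y_pred differ in length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop_invalid("labels must lie in {0, 1}")
  m <- table(factor(y_true, levels = c(0, 1)),
             factor(y_pred, levels = c(0, 1)))
  confusion2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

#' @rdname confusion_matrix
#' @param n00,n01,n10,n11 the four counts `n[actual][predicted]`, e.g.
#'   `n01` is the number of class-0 samples predicted as class 1.
#' @export
confusion2x2 <- function(n00, n01, n10, n11) {
  counts <- c(n00, n01, n10, n11)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_invalid("confusion counts must be non-negative integers")
  if (sum(counts) == 0) stop_invalid("confusion matrix is empty")
  structure(matrix(as.integer(counts), 2L, 2L, byrow = TRUE,
                   dimnames = list(actual = c("0", "1"),
                                   predicted = c("0", "1"))),
            class = c("confusion2x2", "matrix", "array"))
}

#' @export
print.confusion2x2 <- function(x, ...) {
  cat("Confusion matrix (rows = actual, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class classification metrics
#'
#' Treating class `k` as positive: recall (sensitivity) `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`, F-score
#' `2PR/(P+R)`, G-measure `sqrt(P*R)` (the geometric mean of precision and
#' recall), and overall accuracy `(TP+TN)/n`.  In the binary case the
#' specificity for class `k` equals the recall of class `1-k`.  When no
#' sample is predicted positive, precision (and hence F and G) is reported
#' as 0 with `precision_undefined = TRUE` rather than `NaN`, so macro
#' averages stay defined.
#'
#' @param cm a `"confusion2x2"`.
#' @param k the positive class, 0 or 1.
#' @return Named list: `accuracy`, `recall`, `specificity`, `precision`,
#'   `f_score`, `g_measure` (fractions in \[0, 1\]), and
#'   `precision_undefined`.
#' @export
#' @examples
#' class_metrics(confusion2x2(8, 0, 2, 2), k = 0)
class_metrics <- function(cm, k) {
  stopifnot(inherits(cm, "confusion2x2"), k %in% c(0, 1))
  pos <- as.character(k); neg <- as.character(1 - k)
  TP <- cm[pos, pos]; FN <- cm[pos, neg]
  FP <- cm[neg, pos]; TN <- cm[neg, neg]
  if (TP + FN == 0)
    stop_invalid("recall undefined: no actual samples of class ", k)
  recall <- TP / (TP + FN)
  specificity <- if (TN + FP > 0) TN / (TN + FP) else 0
  undef <- (TP + FP) == 0
  precision <- if (undef) 0 else TP / (TP + FP)
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  g <- sqrt(precision * recall)
  list(accuracy = (TP + TN) / sum(cm), recall = recall,
       specificity = specificity, precision = precision,
       f_score = f, g_measure = g, precision_undefined = undef)
}

#' Per-class and macro-averaged metrics report
#'
#' Computes [class_metrics()] for both classes plus their unweighted means
#' (macro averages).  Accuracy is by construction identical for both
#' classes and equals the overall accuracy.
#'
#' @param cm a `"confusion2x2"` with both actual classes present.
#' @return A `"metrics_report"`: list with `per_class` (data frame, one row
#'   per class), `macro` (named numeric vector), and `cm`.  All values are
#'   fractions; [report_table()] and the print method render percentages.
#' @export
#' @examples
#' macro_metrics(confusion2x2(12, 1, 1, 5))
macro_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion2x2"))
  if (any(rowSums(cm) == 0))
    stop_invalid("both actual classes must be present")
  keys <- c("accuracy", "recall", "specificity", "precision",
            "f_score", "g_measure")
  m0 <- class_metrics(cm, 0)
  m1 <- class_metrics(cm, 1)
  per <- rbind(as.data.frame(m0[keys]), as.data.frame(m1[keys]))
  rownames(per) <- c("class_0", "class_1")
  macro <- colMeans(per)
  structure(list(per_class = per, macro = macro, cm = cm),
            class = "metrics_report")
}

#' Render a metrics report as a percent table
#'
#' Percentages rounded half-up to two decimals, one row per class plus the
#' macro average, in the conventional column order (accuracy, recall,
#' specificity, F-score, G-measure, precision).
#'
#' @param report a `"metrics_report"`.
#' @return A data frame of percentages.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  tab <- rbind(report$per_class, average = report$macro)
  tab <- tab[, c("accuracy", "recall", "specificity",
                 "f_score", "g_measure", "precision")]
  as.data.frame(lapply(tab, function(v) round_half_up(100 * v, 2)),
                row.names = rownames(tab))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification metrics (%):\n")
  print(report_table(x)[, 1:5])
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes both a human-readable percent table (`<path>.txt`) and a
#' machine-readable JSON file (`<path>.json`) holding the raw fractions and
#' confusion counts.
#'
#' @param report a `"metrics_report"`.
#' @param path output path prefix (extensions are appended).
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  txt <- paste0(path, ".txt")
  con <- file(txt, "w"); on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  jsonlite::write_json(
    list(per_class = report$per_class, macro = as.list(report$macro),
         confusion = unclass(report$cm)),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Seeded stratified k-fold partition
#'
#' Shuffles each class independently under the seed and deals samples
#' round-robin into `k` folds, so per-fold class counts deviate from exact
#' proportionality by at most one.  A class with fewer than `k` samples
#' yields folds without that class (best effort, with a warning).
#'
#' @param labels 0/1 class labels.
#' @param k number of folds, `2 <= k <= length(labels)`.
#' @param seed integer seed.
#' @return List of `k` integer vectors of test indices: pairwise disjoint,
#'   jointly covering all samples.
#' @export
#' @examples
#' stratified_kfold(rep(c(0, 1), 10), k = 10, seed = 1)
stratified_kfold <- function(labels, k, seed = 1) {
  n <- length(labels)
  if (k < 2 || k > n) stop_invalid("k must lie in [2, n]")
  if (any(table(labels) < k))
    warning("a class has fewer than k samples; stratification is best-effort")
  with_seed(seed, {
    folds <- vector("list", k)
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      assign_to <- rep_len(seq_len(k), length(idx))
      for (f in seq_len(k))
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
    lapply(folds, sort)
  })
}

#' Seeded stratified holdout split
#'
#' @param labels 0/1 class labels.
#' @param test_fraction fraction of each class held out for testing.
#' @param seed integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_holdout <- function(labels, test_fraction = 0.3, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_invalid("test_fraction must lie strictly inside (0, 1)")
  with_seed(seed, {
    test <- integer(0)
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      n_test <- max(1L, round(length(idx) * test_fraction))
      test <- c(test, idx[seq_len(n_test)])
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}
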