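#' Confusion matrix from label vectors
#'
#' Rows are true classes, columns predicted classes; entry `(i, j)` counts
#' samples of true class `i` predicted as class `j`. Class indices are
#' 0-based, matching the dataset-index convention.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors with
#'   values in `0..K-1`.
#' @param K Number of classes.
#' @param class_names Optional character vector of length `K`.
#' @return An object of class `confusion_matrix`: integer `K x K` matrix
#'   with class names on both dimnames.
#' @export
confusion <- function(true_labels, predicted_labels, K,
                      class_names = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  K <- as.integer(K)
  for (v in list(true = true_labels, predicted = predicted_labels)) {
    bad <- which(v < 0 | v > K - 1 | v != round(v))
    if (length(bad))
      stop(sprintf("label out of range 0..%d at position %d (value %s)",
                   K - 1, bad[1], format(v[bad[1]])), call. = FALSE)
  }
  if (is.null(class_names)) class_names <- paste0("class", 0:(K - 1))
  stopifnot(length(class_names) == K)
  counts <- table(factor(true_labels, levels = 0:(K - 1)),
                  factor(predicted_labels, levels = 0:(K - 1)))
  m <- matrix(as.integer(counts), K, K,
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_confusion <- function(m, class_names = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  if (!is.null(class_names))
    dimnames(m) <- list(true = class_names, predicted = class_names)
  else if (is.null(dimnames(m)))
    dimnames(m) <- list(true = paste0("class", 0:(nrow(m) - 1)),
                        predicted = paste0("class", 0:(nrow(m) - 1)))
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stop("undefined metric: empty confusion matrix",
                         call. = FALSE)
  invisible(cm)
}

#' Multiclass accuracy
#'
#' Correct predictions over total predictions: the matrix trace divided by
#' the grand total.
#'
#' @param cm A [confusion()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

per_class_pr_re <- function(cm, warn = c("precision", "recall")) {
  tp <- diag(cm)
  pred <- colSums(cm)
  supp <- rowSums(cm)
  pr <- ifelse(pred > 0, tp / pred, 0)
  re <- ifelse(supp > 0, tp / supp, 0)
  if ("precision" %in% warn && any(pred == 0))
    warning("class never predicted: precision set to 0 for ",
            paste(rownames(cm)[pred == 0], collapse = ", "), call. = FALSE)
  if ("recall" %in% warn && any(supp == 0))
    warning("class with zero support: recall set to 0 for ",
            paste(rownames(cm)[supp == 0], collapse = ", "), call. = FALSE)
  list(precision = pr, recall = re)
}

#' Macro-averaged precision and recall
#'
#' One-vs-rest precision (recall) per class, averaged without class weights.
#' A class that is never predicted contributes precision 0; a class with no
#' support contributes recall 0 (each with a warning).
#'
#' @param cm A [confusion()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
macro_precision <- function(cm) {
  check_cm(cm)
  mean(per_class_pr_re(cm, warn = "precision")$precision)
}

#' @rdname macro_precision
#' @export
macro_recall <- function(cm) {
  check_cm(cm)
  mean(per_class_pr_re(cm, warn = "recall")$recall)
}

#' F1 from macro-averaged precision and recall
#'
#' Harmonic mean `2 * Pr * Re / (Pr + Re)` of the macro averages (not the
#' mean of per-class F1 values: only the harmonic-of-macros convention
#' reproduces the reference results). Returns 0 when both inputs are 0.
#'
#' @param macro_pr,macro_re Fractions in `[0, 1]`.
#' @return Fraction in `[0, 1]`.
#' @export
f1_from_macros <- function(macro_pr, macro_re) {
  if (macro_pr + macro_re <= 0) return(0)
  2 * macro_pr * macro_re / (macro_pr + macro_re)
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero, the convention used when
#' reporting percentages (base R's `round` rounds ties to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full metrics report
#'
#' Accuracy, per-class and macro-averaged precision/recall, and the F1 score
#' computed as the harmonic mean of the macro averages.
#'
#' @param cm A [confusion()] matrix.
#' @return A `metrics_report`: list with `accuracy`, `per_class_precision`,
#'   `per_class_recall`, `per_class_f1`, `macro_precision`, `macro_recall`,
#'   `f1`.
#' @export
report <- function(cm) {
  check_cm(cm)
  pcr <- per_class_pr_re(cm)
  pr <- pcr$precision; re <- pcr$recall
  f1c <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  mp <- mean(pr); mr <- mean(re)
  structure(list(accuracy = accuracy(cm),
                 per_class_precision = pr, per_class_recall = re,
                 per_class_f1 = f1c,
                 macro_precision = mp, macro_recall = mr,
                 f1 = f1_from_macros(mp, mr)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", round_half_up(100 * v, 2))
  cat("accuracy:       ", pct(x$accuracy), "\n")
  cat("macro precision:", pct(x$macro_precision), "\n")
  cat("macro recall:   ", pct(x$macro_recall), "\n")
  cat("F1 (of macros): ", pct(x$f1), "\n")
  invisible(x)
}

#' Read / write confusion matrices as CSV
#'
#' Square CSV with a header row and a leading column of class names.
#'
#' @param cm A [confusion()] matrix.
#' @param path File path.
#' @return `write_confusion_csv` returns `path` invisibly;
#'   `read_confusion_csv` returns a `confusion_matrix`.
#' @export
write_confusion_csv <- function(cm, path) {
  stopifnot(inherits(cm, "confusion_matrix"))
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(df), class_names = rownames(df))
}

#' Write a metrics report as JSON
#'
#' @param rep A [report()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(rep, path) {
  stopifnot(inherits(rep, "metrics_report"))
  jsonlite::write_json(lapply(unclass(rep), unname), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
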