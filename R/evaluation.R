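# Classifier evaluation: confusion matrix (actual species in rows, predicted
# in columns), accuracy with an exact binomial CI, Cohen's kappa, the
# no-information rate, and per-class sensitivity/precision.

#' Confusion matrix
#'
#' @param actual,predicted Equal-length label vectors.
#' @param class_labels Class vocabulary (default: sorted union).
#' @return K x K integer matrix; entry (i, j) counts seeds of actual class i
#'   predicted as class j. Actual species in rows, predictions in columns.
#' @export
confusion_matrix <- function(actual, predicted, class_labels = NULL) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have the same length")
  if (is.null(class_labels)) class_labels <- sort(unique(c(actual, predicted)))
  bad <- setdiff(unique(c(actual, predicted)), class_labels)
  if (length(bad) > 0L)
    stop("label(s) outside the class vocabulary: ", paste(bad, collapse = ", "))
  a <- factor(actual, levels = class_labels)
  p <- factor(predicted, levels = class_labels)
  unclass(table(actual = a, predicted = p))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval for a proportion from beta quantiles:
#' `lower = qbeta(alpha/2, s, n - s + 1)`, `upper = qbeta(1 - alpha/2,
#' s + 1, n - s)`, with `lower = 0` when `s = 0` and `upper = 1` when
#' `s = n`.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' accuracy_ci(800, 859)   # c(0.9123, 0.9473) at 4 decimal places
#' @export
accuracy_ci <- function(successes, n, level = 0.95) {
  if (n < 1L || successes < 0L || successes > n || is.na(successes))
    stop("need 0 <= successes <= n with n >= 1")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' accuracy `p_o = trace/n` and expected accuracy
#' `p_e = sum_k row_k * col_k / n^2`. The degenerate case `p_e = 1` is
#' defined as 1 when `p_o = 1` and 0 otherwise.
#'
#' @param confusion Square count matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (length(confusion) == 0L || n < 1) stop("empty confusion matrix")
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (1 - p_e <= .Machine$double.eps) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' No-information rate
#'
#' Accuracy achievable by always predicting the most frequent actual class.
#'
#' @param actual Non-empty label vector.
#' @return Proportion in (0, 1].
#' @export
no_information_rate <- function(actual) {
  if (length(actual) == 0L) stop("`actual` must be non-empty")
  max(table(actual)) / length(actual)
}

#' Evaluate predictions against truth
#'
#' @param actual,predicted Label vectors of equal length.
#' @param class_labels Class vocabulary (default: sorted union).
#' @param level Confidence level for the accuracy CI.
#' @return An `evaluation_report`: confusion matrix, `n`, `accuracy`,
#'   `ci_low`/`ci_high` (exact binomial), `kappa`, `nir`, and a `per_class`
#'   data frame of sensitivity and precision.
#' @export
evaluate_classifier <- function(actual, predicted, class_labels = NULL,
                                level = 0.95) {
  cm <- confusion_matrix(actual, predicted, class_labels)
  n <- sum(cm)
  correct <- sum(diag(cm))
  ci <- accuracy_ci(correct, n, level)
  per_class <- data.frame(
    class = rownames(cm),
    sensitivity = ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_),
    precision = ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = cm, n = n, accuracy = correct / n,
                 ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                 kappa = cohen_kappa(cm), nir = no_information_rate(actual),
                 level = level, per_class = per_class),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("Model statistics\n")
  cat(sprintf("  Accuracy                          %.*f\n", digits, x$accuracy))
  cat(sprintf("  %g%% confidence interval of accuracy (%.*f, %.*f)\n",
              100 * x$level, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  No information rate               %.*f\n", digits, x$nir))
  cat(sprintf("  Kappa                             %.*f\n", digits, x$kappa))
  cat(sprintf("  Size of data set                  %d observations\n", x$n))
  cat("Confusion matrix (actual in rows, predicted in columns):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param path JSON file path.
#' @return `report_to_json` returns `path` invisibly; `report_from_json` the
#'   restored report.
#' @export
report_to_json <- function(report, path) {
  payload <- unclass(report)
  payload$confusion <- list(labels = rownames(report$confusion),
                            counts = unname(report$confusion))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname report_to_json
#' @export
report_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(p$confusion$counts)
  dimnames(cm) <- list(actual = p$confusion$labels,
                       predicted = p$confusion$labels)
  structure(list(confusion = cm, n = p$n, accuracy = p$accuracy,
                 ci_low = p$ci_low, ci_high = p$ci_high, kappa = p$kappa,
                 nir = p$nir, level = p$level,
                 per_class = as.data.frame(p$per_class)),
            class = "evaluation_report")
}
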