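#' @title Classification metrics and statistical comparison
#'
#' @description
#' Precision, recall and F1 with the 0/0 -> 0 convention (degenerate
#' counts arise when a category is rare in a small test split),
#' per-subject / per-category aggregation of F1 tables, and Welch's
#' unequal-variance two-sample t-test with Welch-Satterthwaite degrees
#' of freedom for comparing methods.
#'
#' @name evaluation
NULL

#' Confusion counts from true and predicted binary labels
#'
#' @param truth,pred Binary vectors (0/1) of equal length.
#' @return A `confusion_counts`: named integer vector with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop("lengths differ", call. = FALSE)
  if (!all(c(truth, pred) %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  structure(c(tp = sum(truth == 1L & pred == 1L),
              fp = sum(truth == 0L & pred == 1L),
              fn = sum(truth == 1L & pred == 0L),
              tn = sum(truth == 0L & pred == 0L)),
            class = "confusion_counts")
}

#' Precision, recall and F1-measure
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 * recall * precision / (recall + precision)`; any 0/0 is 0
#' by convention.
#'
#' @param counts A [confusion_counts()] or named vector with `tp`,
#'   `fp`, `fn`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- as.numeric(counts[["tp"]])
  fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]])
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (recall + precision == 0) 0 else 2 * recall * precision / (recall + precision)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Welch's unequal-variance two-sample t-test
#'
#' `t = (mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param a,b Numeric samples, each with at least 2 values and positive
#'   variance.
#' @return Named numeric vector `c(t, df, p)`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va <= 0 || vb <= 0) stop("samples must have positive variance", call. = FALSE)
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  c(t = t_stat, df = df, p = p)
}

#' Aggregate a subject-by-category F1 table
#'
#' @param f1 Numeric matrix, rows = subjects, columns = categories; no
#'   missing cells.
#' @return A `result_table`: list with the `cells` matrix,
#'   `subject_means`, `category_means`, `grand_mean` (identical under
#'   either grouping on a rectangular table).
#' @export
aggregate_f1 <- function(f1) {
  f1 <- as.matrix(f1)
  if (any(!is.finite(f1))) stop("missing or non-finite cells", call. = FALSE)
  structure(list(cells = f1,
                 subject_means = rowMeans(f1),
                 category_means = colMeans(f1),
                 grand_mean = mean(f1)),
            class = "result_table")
}
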