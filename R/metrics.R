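#' Confusion counts for binary detection
#'
#' Container for the four confusion-matrix tallies feeding every
#' classification metric. Construct either from explicit counts or from
#' actual/predicted 0-1 label vectors via [tabulate_confusion()].
#'
#' @param tp,tn,fp,fn Non-negative integer counts (true positives, true
#'   negatives, false positives, false negatives).
#' @return An object of class `"confusion_counts"`.
#' @examples
#' confusion_counts(tp = 90, tn = 80, fp = 10, fn = 20)
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("confusion counts must be finite and non-negative", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Tally confusion counts from label vectors
#'
#' @param actual,predicted Vectors of 0/1 labels (positive class = 1).
#' @return A `"confusion_counts"` object.
#' @export
tabulate_confusion <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  actual <- as.integer(actual)
  predicted <- as.integer(predicted)
  if (!all(actual %in% 0:1) || !all(predicted %in% 0:1)) {
    stop("labels must be 0/1 for binary confusion counts", call. = FALSE)
  }
  confusion_counts(
    tp = sum(actual == 1 & predicted == 1),
    tn = sum(actual == 0 & predicted == 0),
    fp = sum(actual == 0 & predicted == 1),
    fn = sum(actual == 1 & predicted == 0)
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts:  TP", x$tp, " TN", x$tn, " FP", x$fp, " FN", x$fn, "\n")
  invisible(x)
}

check_counts <- function(c) {
  if (!inherits(c, "confusion_counts")) {
    stop("expected a confusion_counts object", call. = FALSE)
  }
  if (c$tp + c$tn + c$fp + c$fn <= 0) {
    stop("confusion counts are all zero", call. = FALSE)
  }
  invisible(c)
}

#' Classification metrics
#'
#' Exact confusion-matrix metric formulas, all returned as fractions in
#' `[0, 1]` (MCC in `[-1, 1]`); percent scaling is a presentation concern
#' (see `percent` in [classification_report()]).
#'
#' * `accuracy`: (TP + TN) / total.
#' * `precision`: TP / (TP + FP).
#' * `f1_score`: 2 TP / (2 TP + FP + FN).
#' * `mcc`: Matthews correlation coefficient; returns 0 when any marginal
#'   is zero (the standard limit convention).
#' * `csi`: critical success index TP / (TP + FP + FN).
#' * `fpr`: false positive rate FP / (FP + TN).
#'
#' @param c A [confusion_counts()] object.
#' @return A scalar metric value.
#' @name classification_metrics
NULL

#' @rdname classification_metrics
#' @export
accuracy <- function(c) {
  check_counts(c)
  (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)
}

#' @rdname classification_metrics
#' @export
precision <- function(c) {
  check_counts(c)
  if (c$tp + c$fp == 0) stop("precision undefined: no predicted positives", call. = FALSE)
  c$tp / (c$tp + c$fp)
}

#' @rdname classification_metrics
#' @export
f1_score <- function(c) {
  check_counts(c)
  if (2 * c$tp + c$fp + c$fn == 0) stop("f1 undefined: no positives anywhere", call. = FALSE)
  2 * c$tp / (2 * c$tp + c$fp + c$fn)
}

#' @rdname classification_metrics
#' @export
mcc <- function(c) {
  check_counts(c)
  den2 <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (den2 == 0) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(den2)
}

#' @rdname classification_metrics
#' @export
csi <- function(c) {
  check_counts(c)
  if (c$tp + c$fp + c$fn == 0) stop("csi undefined: TP + FP + FN is zero", call. = FALSE)
  c$tp / (c$tp + c$fp + c$fn)
}

#' @rdname classification_metrics
#' @export
fpr <- function(c) {
  check_counts(c)
  if (c$fp + c$tn == 0) stop("fpr undefined: no actual negatives", call. = FALSE)
  c$fp / (c$fp + c$tn)
}

check_pair <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) < 1L) stop("empty regression pair", call. = FALSE)
  if (!all(is.finite(actual)) || !all(is.finite(predicted))) {
    stop("regression pair contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Regression error metrics
#'
#' Error measures for AF-rate regression, all as fractions of the target
#' scale (no percent scaling).
#'
#' * `rmse`: root mean squared error.
#' * `mae`: mean absolute error.
#' * `smape`: symmetric mean absolute percentage error with the
#'   mean-of-endpoints denominator `(|predicted| + |actual|) / 2`, bounded
#'   by 2; a term with both values zero contributes 0 (limit convention).
#' * `mpe`: mean of `|predicted - actual| / actual` — despite the "mean
#'   percentage error" name this is the absolute-percentage (MAPE-style)
#'   form, implemented exactly as defined; requires all actual values
#'   nonzero.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @name regression_metrics
NULL

#' @rdname regression_metrics
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname regression_metrics
#' @export
mae <- function(actual, predicted) {
  check_pair(actual, predicted)
  mean(abs(actual - predicted))
}

#' @rdname regression_metrics
#' @export
smape <- function(actual, predicted) {
  check_pair(actual, predicted)
  den <- (abs(predicted) + abs(actual)) / 2
  term <- abs(predicted - actual) / den
  term[den == 0] <- 0
  mean(term)
}

#' @rdname regression_metrics
#' @export
mpe <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (any(actual == 0)) {
    stop("mpe undefined: actual values contain zero", call. = FALSE)
  }
  mean(abs(predicted - actual) / actual)
}

#' All classification metrics at once
#'
#' Metrics whose denominator is zero for the given counts (e.g. precision
#' with no predicted positives) are reported as `NA` rather than erroring,
#' so a degenerate classifier still yields a report.
#'
#' @param c A [confusion_counts()] object.
#' @param percent Report the `[0, 1]`-valued metrics as percentages
#'   (MCC is left on its natural `[-1, 1]` scale).
#' @return Named numeric vector with accuracy, precision, f1, mcc, csi, fpr.
#' @export
classification_report <- function(c, percent = FALSE) {
  safely <- function(f) tryCatch(f(c), error = function(e) NA_real_)
  out <- c(accuracy = safely(accuracy), precision = safely(precision),
           f1 = safely(f1_score), mcc = safely(mcc), csi = safely(csi),
           fpr = safely(fpr))
  if (percent) {
    scale_up <- c("accuracy", "precision", "f1", "csi", "fpr")
    out[scale_up] <- out[scale_up] * 100
  }
  out
}

#' All regression metrics at once
#'
#' @inheritParams regression_metrics
#' @param percent Scale smape and mpe by 100.
#' @return Named numeric vector with rmse, mae, smape, mpe (mpe is `NA`
#'   when any actual value is zero).
#' @export
regression_report <- function(actual, predicted, percent = FALSE) {
  out <- c(rmse = rmse(actual, predicted),
           mae = mae(actual, predicted),
           smape = smape(actual, predicted),
           mpe = if (any(actual == 0)) NA_real_ else mpe(actual, predicted))
  if (percent) out[c("smape", "mpe")] <- out[c("smape", "mpe")] * 100
  out
}
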