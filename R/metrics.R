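# Evaluation statistics: recognition accuracy, confusion-count F1 and the
# coefficient of determination.

#' Aggregate confusion counts for single-label classification
#'
#' Micro aggregation over classes: `N_TP` counts correct predictions; every
#' misclassification is simultaneously one false positive (for the
#' predicted class) and one false negative (for the true class).
#'
#' @param truth,pred Equal-length label vectors.
#' @return A `confusion_counts` list: `N_TP`, `N_FP`, `N_FN`, `N_data`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred))
    abort_input("truth and pred must have equal length")
  tp <- sum(truth == pred)
  structure(list(N_TP = tp, N_FP = length(truth) - tp,
                 N_FN = length(truth) - tp, N_data = length(truth)),
            class = "confusion_counts")
}

#' Recognition accuracy
#'
#' `RA = N_TP / N_data`: the fraction of test samples classified
#' correctly.
#'
#' @param counts A `confusion_counts` list (or any list with `N_TP` and
#'   `N_data`).
#' @return RA in `[0, 1]`.
#' @export
recognition_accuracy <- function(counts) {
  if (is.null(counts$N_data) || counts$N_data == 0)
    abort_input("N_data must be positive")
  counts$N_TP / counts$N_data
}

#' F1 score from confusion counts
#'
#' Micro form exactly as `F1 = 2 N_TP / (2 N_TP + N_FP + N_FN)`. When
#' given label vectors, `average = "micro"` aggregates counts over classes
#' first, while `average = "macro"` computes a per-class F1 (one-vs-rest)
#' and averages the class scores.
#'
#' @param x A `confusion_counts` list, or a truth label vector (then
#'   `pred` is required).
#' @param pred Predicted labels when `x` is a truth vector.
#' @param average `"micro"` or `"macro"` (label-vector input only).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(x, pred = NULL, average = c("micro", "macro")) {
  average <- match.arg(average)
  if (inherits(x, "confusion_counts") || (is.list(x) && !is.null(x$N_TP))) {
    denom <- 2 * x$N_TP + x$N_FP + x$N_FN
    if (denom == 0) abort_input("F1 undefined: all confusion counts are zero")
    return(2 * x$N_TP / denom)
  }
  truth <- x
  if (is.null(pred)) abort_input("pred labels are required")
  if (average == "micro") return(f1_score(confusion_counts(truth, pred)))
  classes <- sort(unique(c(truth, pred)))
  per_class <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(per_class, na.rm = TRUE)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; equals 1 iff the
#' predictions are exact, 0 for the constant mean predictor, and is
#' undefined when the true series has zero variance.
#'
#' @param y_act True value sequence.
#' @param y_pre Prediction sequence of the same length.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(y_act, y_pre) {
  if (length(y_act) != length(y_pre))
    abort_input("sequences must have equal length")
  ss_tot <- sum((y_act - mean(y_act))^2)
  if (ss_tot == 0) abort_input("R^2 undefined: y_act has zero variance")
  1 - sum((y_act - y_pre)^2) / ss_tot
}

#' Assemble a per-head metrics report
#'
#' @param truth,pred Label vectors (0-based levels).
#' @return List with `ra`, `f1_micro`, `f1_macro`, `r_squared` (levels
#'   treated as an ordinal scale), and the raw `counts`.
#' @export
metrics_report <- function(truth, pred) {
  counts <- confusion_counts(truth, pred)
  list(
    ra = recognition_accuracy(counts),
    f1_micro = f1_score(counts),
    f1_macro = f1_score(truth, pred, average = "macro"),
    r_squared = if (stats::var(truth) > 0) r_squared(truth, pred) else NA_real_,
    counts = counts
  )
}
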