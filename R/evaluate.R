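#' Confusion matrix for binary survival predictions
#'
#' Class 1 is "survived"; positives are predicted survivors.
#'
#' @param y_true,y_pred binary 0/1 vectors of equal length.
#' @return list of counts `tn`, `fp`, `fn`, `tp`, class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  structure(list(tn = sum(y_true == 0 & y_pred == 0),
                 fp = sum(y_true == 0 & y_pred == 1),
                 fn = sum(y_true == 1 & y_pred == 0),
                 tp = sum(y_true == 1 & y_pred == 1)),
            class = "confusion_matrix")
}

# Ratio that reports 0 with an "undefined" flag when the denominator is 0,
# matching the usual macro-averaging convention.
safe_ratio <- function(num, den) {
  if (den == 0) structure(0, undefined = TRUE) else num / den
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, per-class precision/recall/F1, specificity (class-0 recall),
#' and macro-averaged F1. Metrics with a zero denominator are reported as 0
#' with an `undefined` flag and counted as 0 in the macro average.
#'
#' @param cm a [confusion()] result, or a list with `tn`, `fp`, `fn`, `tp`.
#' @return list of metrics, class `metrics_report`.
#' @export
class_metrics <- function(cm) {
  total <- cm$tn + cm$fp + cm$fn + cm$tp
  if (total == 0) stop("empty confusion matrix")
  f1 <- function(prec, rec) {
    if (prec + rec == 0) structure(0, undefined = TRUE)
    else 2 * prec * rec / (prec + rec)
  }
  precision_1 <- safe_ratio(cm$tp, cm$tp + cm$fp)
  recall_1 <- safe_ratio(cm$tp, cm$tp + cm$fn)
  precision_0 <- safe_ratio(cm$tn, cm$tn + cm$fn)
  recall_0 <- safe_ratio(cm$tn, cm$tn + cm$fp)
  f1_1 <- f1(precision_1, recall_1)
  f1_0 <- f1(precision_0, recall_0)
  structure(list(accuracy = (cm$tn + cm$tp) / total,
                 precision_0 = precision_0, recall_0 = recall_0, f1_0 = f1_0,
                 precision_1 = precision_1, recall_1 = recall_1, f1_1 = f1_1,
                 specificity = recall_0,
                 macro_f1 = (as.numeric(f1_0) + as.numeric(f1_1)) / 2),
            class = "metrics_report")
}

#' Macro-averaged F1 score
#'
#' @param y_true,y_pred binary 0/1 vectors.
#' @export
macro_f1 <- function(y_true, y_pred) {
  class_metrics(confusion(y_true, y_pred))$macro_f1
}

#' Brier score
#'
#' Mean squared difference between predicted survival probabilities and
#' binary outcomes; 0 is perfect, the constant-0.5 predictor scores 0.25.
#'
#' @param probs predicted survival probabilities in \[0, 1\].
#' @param y_true binary outcomes.
#' @export
brier <- function(probs, y_true) {
  if (length(probs) != length(y_true)) stop("length mismatch")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs - y_true)^2)
}

#' Classification-threshold sweep maximizing macro-F1
#'
#' Evaluates 100 evenly spaced thresholds on \[0.40, 0.70\] (endpoints
#' included); at each, class 1 is predicted when the probability is >= the
#' threshold. The optimal threshold is the smallest grid value attaining
#' the maximal macro-F1.
#'
#' @param probs predicted survival probabilities.
#' @param y_true binary outcomes (both classes must be present).
#' @param range threshold interval.
#' @param n grid size.
#' @return list: `grid`, `macro_f1`, `optimal` (tau*), class
#'   `threshold_curve`.
#' @export
threshold_sweep <- function(probs, y_true, range = c(0.40, 0.70), n = 100) {
  if (length(unique(y_true)) < 2)
    stop("threshold sweep needs both classes in y_true")
  grid <- seq(range[1], range[2], length.out = n)
  f1s <- vapply(grid, function(tau)
    macro_f1(y_true, as.integer(probs >= tau)), numeric(1))
  structure(list(grid = grid, macro_f1 = f1s,
                 optimal = grid[which.max(f1s)]),
            class = "threshold_curve")
}
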