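resolve_truth <- function(predictions, truth_col) {
  tr <- predictions[[truth_col]]
  if (is.null(tr) && truth_col == "positive" && "label" %in% names(predictions))
    abort("no 'positive' column; supply truth_col or add a logical positive column")
  if (!is.logical(tr)) tr <- as.logical(tr)
  tr
}

check_two_classes <- function(truth) {
  if (all(truth)) abort("cannot compute curve metrics: no negative nights present")
  if (!any(truth)) abort("cannot compute curve metrics: no positive nights present")
}

#' Area under the ROC curve of nightly predictions
#'
#' Computed via the rank (Mann-Whitney) formulation with midrank tie
#' correction, which equals trapezoidal integration of the ROC curve and a
#' brute-force concordance count over all positive/negative pairs (ties
#' counted 1/2).
#'
#' @param predictions Tibble of nightly predictions.
#' @param score_col Column holding predicted probabilities.
#' @param truth_col Logical column: `TRUE` for positive nights.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(predictions, score_col = "p_hat", truth_col = "positive") {
  score <- predictions[[score_col]]
  truth <- resolve_truth(predictions, truth_col)
  check_two_classes(truth)
  r <- rank(score)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration: thresholds are placed at each distinct score
#' (descending); the curve takes precision at each achieved recall level and
#' the area is the sum of precision times recall increment (no linear
#' interpolation between operating points). For a constant score the curve
#' collapses to a single point and the area equals the outcome prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(predictions, score_col = "p_hat", truth_col = "positive") {
  score <- predictions[[score_col]]
  truth <- resolve_truth(predictions, truth_col)
  check_two_classes(truth)
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; truth <- truth[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(truth)[last_of_tie]
  n_called <- seq_along(score)[last_of_tie]
  recall <- tp / sum(truth)
  precision <- tp / n_called
  sum(diff(c(0, recall)) * precision)
}

#' Thresholded classification metrics for nightly predictions
#'
#' Classifies a night as positive when its predicted probability is at or
#' above the threshold (ties called positive, so 0.5 behaves as the usual
#' default cut) and reports precision, accuracy, sensitivity and
#' specificity. Precision is defined as 0 (with `no_positive_calls = TRUE`)
#' when no night is called positive.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold in `(0, 1)`, e.g. 0.25, 0.5, 0.75.
#' @return A one-row tibble with the threshold, the four rates, the
#'   confusion counts, positive days and total days.
#' @export
threshold_metrics <- function(predictions, threshold,
                              score_col = "p_hat", truth_col = "positive") {
  stopifnot(threshold > 0, threshold < 1)
  score <- predictions[[score_col]]
  truth <- resolve_truth(predictions, truth_col)
  called <- score >= threshold
  tp <- sum(called & truth); fp <- sum(called & !truth)
  fn <- sum(!called & truth); tn <- sum(!called & !truth)
  tibble(
    threshold = threshold,
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    tp = tp, fp = fp, tn = tn, fn = fn,
    no_positive_calls = tp + fp == 0,
    positive_days = tp + fn,
    total_days = length(truth)
  )
}

#' Recover a confusion matrix from published summary rates
#'
#' Inverts printed sensitivity/specificity and class counts back to integer
#' confusion counts: `tp = round(sens * n_pos)`, `tn = round(spec * n_neg)`,
#' with the complements as errors. The derived rates are compared back to
#' the inputs; disagreement beyond rounding slack (`1 / (2 * count)`) sets
#' `consistent = FALSE`. Useful for checking the internal arithmetic of
#' published threshold-metric tables.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param n_pos,n_neg Positive / negative day counts.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, derived `precision`
#'   and `accuracy`, and a `consistent` flag.
#' @export
confusion_from_summary <- function(sensitivity, specificity, n_pos, n_neg) {
  if (n_pos < 0 || n_neg < 0) abort("counts must be non-negative")
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  tp <- round(sensitivity * n_pos); fn <- n_pos - tp
  tn <- round(specificity * n_neg); fp <- n_neg - tn
  sens_back <- if (n_pos > 0) tp / n_pos else NA_real_
  spec_back <- if (n_neg > 0) tn / n_neg else NA_real_
  ok <- (n_pos == 0 || abs(sens_back - sensitivity) <= 1 / (2 * n_pos)) &&
        (n_neg == 0 || abs(spec_back - specificity) <= 1 / (2 * n_neg))
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         precision = if (tp + fp == 0) 0 else tp / (tp + fp),
         accuracy = (tp + tn) / max(n_pos + n_neg, 1),
         consistent = ok)
}

#' Accuracy from sensitivity, specificity and prevalence
#'
#' The identity `accuracy = sensitivity * prevalence + specificity *
#' (1 - prevalence)`.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @param prevalence Positive-class prevalence in `[0, 1]`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_summary <- function(sensitivity, specificity, prevalence) {
  sensitivity * prevalence + specificity * (1 - prevalence)
}
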