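#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Equal-length binary vectors (1 = breathing).
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("          pred 1  pred 0\ntrue 1  %7d %7d\ntrue 0  %7d %7d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NaN else num / den

#' Classification metric report
#'
#' Top-1 accuracy, precision, recall (= sensitivity), F1, specificity and —
#' when continuous scores are supplied — AUC from the trapezoidal rule over
#' the empirical ROC curve. Metrics with a zero denominator are reported as
#' `NaN` and listed in the `undefined` field (with a warning) rather than
#' raising, so batch sweeps do not abort.
#'
#' @param counts A `confusion_counts` object.
#' @param scores Optional continuous scores (sigmoid outputs or spike rates)
#'   for AUC.
#' @param y_true True labels matching `scores`; required with `scores`.
#' @param include_auc Compute AUC (default: whenever `scores` is given).
#'   Requesting AUC without scores is an error.
#' @return A `metric_report` list: `top1`, `precision`, `recall`, `f1`,
#'   `sensitivity`, `specificity`, `auc`, `undefined`.
#' @export
all_metrics <- function(counts, scores = NULL, y_true = NULL,
                        include_auc = !is.null(scores)) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total < 1) stop("empty confusion counts", call. = FALSE)
  top1 <- (counts$TP + counts$TN) / total
  precision <- safe_ratio(counts$TP, counts$TP + counts$FP)
  recall <- safe_ratio(counts$TP, counts$TP + counts$FN)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  specificity <- safe_ratio(counts$TN, counts$TN + counts$FP)
  auc <- NA_real_
  if (include_auc) {
    if (is.null(scores)) stop("AUC requested without scores", call. = FALSE)
    if (is.null(y_true)) stop("AUC requires `y_true` alongside `scores`", call. = FALSE)
    auc <- roc_auc(y_true, scores)
  }
  out <- list(top1 = top1, precision = precision, recall = recall, f1 = f1,
              sensitivity = recall, specificity = specificity, auc = auc)
  undefined <- names(out)[vapply(out, function(v) is.nan(v), logical(1))]
  if (length(undefined) > 0) {
    warning("undefined metrics (zero denominator): ",
            paste(undefined, collapse = ", "), call. = FALSE)
  }
  structure(c(out, list(undefined = undefined)), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "top1 %.4f | precision %.4f | recall %.4f | f1 %.4f | specificity %.4f | auc %s\n",
    x$top1, x$precision, x$recall, x$f1, x$specificity,
    if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' Builds the empirical ROC from the score thresholds and integrates with
#' the trapezoidal rule; ties in scores are handled by grouping.
#'
#' @param y_true Binary labels.
#' @param scores Continuous scores, larger = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) {
    stop("`y_true` and `scores` must have equal length", call. = FALSE)
  }
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) return(NaN)
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative TP/FP at each distinct threshold
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last_of_tie] / n_pos)
  fpr <- c(0, fp[last_of_tie] / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Bland-Altman agreement statistics
#'
#' Summarizes paired differences `a - b` between two measurement methods:
#' mean, minimum and maximum difference and the limits of agreement
#' `mean +/- 1.96 sd`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors (length >= 2), e.g.
#'   accuracies of two models across evaluation conditions.
#' @return An `agreement_stats` list: `mean_diff`, `min_diff`, `max_diff`,
#'   `loa_lower`, `loa_upper`, `sd_diff`.
#' @examples
#' bland_altman(c(96, 95, 97), c(93.9, 82.5, 89.7))
#' @export
bland_altman <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  if (length(acc_a) < 2) stop("need at least 2 paired values", call. = FALSE)
  d <- acc_a - acc_b
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, min_diff = min(d), max_diff = max(d),
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 sd_diff = s),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("mean diff %.3f [min %.3f, max %.3f], LoA [%.3f, %.3f]\n",
              x$mean_diff, x$min_diff, x$max_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}
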