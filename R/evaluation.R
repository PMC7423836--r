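#' Confusion matrix of a binary classification
#'
#' Counts with `CTC_POSITIVE` (or `TRUE`, or the value of `positive`) as the
#' positive class: TP = truth positive predicted positive, FN = truth
#' positive predicted negative, FP = truth negative predicted positive,
#' TN = truth negative predicted negative.
#'
#' @param truth,pred equal-length vectors of binary labels (character,
#'   factor or logical).
#' @param positive the positive-class label.
#' @return A `confusion_matrix` with integer fields `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(truth, pred, positive = "CTC_POSITIVE") {
  if (length(truth) != length(pred))
    stopf("truth and pred have different lengths (%d vs %d)",
          length(truth), length(pred))
  if (length(truth) == 0L) stopf("empty label vectors")
  tp_ <- truth == positive; pp_ <- pred == positive
  confusion_matrix(sum(tp_ & pp_), sum(tp_ & !pp_), sum(!tp_ & pp_),
                   sum(!tp_ & !pp_))
}

#' @rdname confusion
#' @param TP,FN,FP,TN non-negative cell counts.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  v <- c(TP, FN, FP, TN)
  if (anyNA(v) || any(v < 0) || any(v != round(v)))
    stopf("counts must be non-negative integers")
  structure(list(TP = as.integer(TP), FN = as.integer(FN),
                 FP = as.integer(FP), TN = as.integer(TN)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("Positive", "Negative"),
                              prediction = c("Positive", "Negative")))
  print(m)
  invisible(x)
}

# Round half away from zero (the convention used for reported percentages;
# base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity (recall) `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)` and the F1 score
#' `2 * precision * recall / (precision + recall)`. A metric with a zero
#' denominator is undefined and reported as `NA` — never coerced to 0 —
#' so degenerate test sets cannot silently score perfect or zero.
#'
#' @param cm a [confusion_matrix].
#' @param auc optional AUC to carry along in the result.
#' @return A `ctc_metrics` list with fields `sensitivity`, `specificity`,
#'   `precision`, `f1` (fractions in \[0, 1\] or `NA`) and optionally `auc`.
#' @export
metrics <- function(cm, auc = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0L) stopf("all-zero confusion matrix")
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  se <- frac(cm$TP, cm$TP + cm$FN)
  sp <- frac(cm$TN, cm$TN + cm$FP)
  prec <- frac(cm$TP, cm$TP + cm$FP)
  f1 <- if (is.na(se) || is.na(prec) || prec + se == 0) NA_real_
        else 2 * prec * se / (prec + se)
  structure(list(sensitivity = se, specificity = sp, precision = prec,
                 f1 = f1, auc = auc, confusion = cm),
            class = "ctc_metrics")
}

#' @export
print.ctc_metrics <- function(x, digits = 1, ...) {
  p <- metrics_pct(x, digits)
  pct <- function(v) if (is.na(v)) "undefined"
                     else sprintf(paste0("%.", digits, "f%%"), v)
  cat(sprintf("Sensitivity (Se): %s\n", pct(p["sensitivity"])))
  cat(sprintf("Specificity (Sp): %s\n", pct(p["specificity"])))
  cat(sprintf("Precision:        %s\n", pct(p["precision"])))
  cat(sprintf("F1 score:         %s\n", pct(p["f1"])))
  if (!is.null(x$auc)) cat(sprintf("AUC:              %.3f\n", x$auc))
  invisible(x)
}

#' Metrics as reported percentages
#'
#' Sensitivity, specificity and precision are rounded half away from zero
#' to `digits` decimals. The reported F1 percentage follows the common
#' reporting convention of recomputing the harmonic mean from the rounded
#' precision and recall percentages (the exact fraction is in `m$f1`).
#'
#' @param m a `ctc_metrics`.
#' @param digits decimals (default 1, half rounded away from zero).
#' @return Named numeric vector of percentages (`NA` where undefined).
#' @export
metrics_pct <- function(m, digits = 1) {
  v <- round_half_up(100 * c(sensitivity = m$sensitivity,
                             specificity = m$specificity,
                             precision = m$precision), digits)
  f1 <- if (is.na(v["sensitivity"]) || is.na(v["precision"]) ||
            v["sensitivity"] + v["precision"] == 0) NA_real_
        else round_half_up(2 * v["precision"] * v["sensitivity"] /
                             (v["precision"] + v["sensitivity"]), digits)
  c(v, f1 = unname(f1))
}

#' ROC curve and AUC
#'
#' AUC by the rank statistic (Mann-Whitney formulation): the probability
#' that a random positive scores above a random negative, ties counting
#' one half. Curve points are computed over all distinct score thresholds.
#'
#' @param scores numeric positive-class scores.
#' @param truth binary labels (see `positive`).
#' @param positive the positive-class label.
#' @return A `roc_curve`: list with `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive = "CTC_POSITIVE") {
  if (length(scores) != length(truth)) stopf("scores and truth lengths differ")
  if (any(!is.finite(scores))) stopf("scores must be finite")
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(scores)                     # mean ranks handle ties as 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pp <- scores >= t
    c(fpr = sum(pp & !pos) / n0, tpr = sum(pp & pos) / n1)
  }, numeric(2)))
  structure(list(points = data.frame(threshold = th, fpr = pts[, "fpr"],
                                     tpr = pts[, "tpr"]),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}
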