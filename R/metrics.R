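# Imbalance-aware evaluation.
#
# NOTE ON THE LABEL CONVENTION: following the source convention of this
# method family, the POSITIVE class is ADL (the majority) and the NEGATIVE
# class is the fall:
#   TP = ADL correctly classified        TN = fall correctly detected
#   FP = fall missed (not detected)      FN = false alarm (ADL flagged)
# Hence "sensitivity" is ADL recall and "specificity" is fall-detection
# recall -- the metric that matters most in fall detection, which is why
# the F-beta score below uses beta = 0.5 (< 1 weights specificity more).

#' Confusion-matrix counts (positive = ADL)
#'
#' @param true_labels,pred_labels 0/1 vectors (0 = ADL, 1 = fall) of equal
#'   length.
#' @return named numeric vector `c(tp, tn, fp, fn)` under the convention
#'   above.
#' @export
confusion <- function(true_labels, pred_labels) {
  t <- as.integer(true_labels); p <- as.integer(pred_labels)
  if (length(t) != length(p))
    stop_imbfall("label vectors must have equal length", "imbfall_value_error")
  c(tp = sum(t == 0L & p == 0L),
    tn = sum(t == 1L & p == 1L),
    fp = sum(t == 1L & p == 0L),
    fn = sum(t == 0L & p == 1L))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (tp + tn) / n`; `sensitivity = tp / (tp + fn)` (ADL
#' recall); `specificity = tn / (tn + fp)` (fall recall). A rate with a
#' zero denominator is undefined and reported as `NA` with a warning,
#' never as 0 or 1.
#'
#' @param counts named vector from [confusion()].
#' @return list with `accuracy`, `sensitivity`, `specificity` as
#'   percentages in `[0, 100]`.
#' @export
rates <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  n <- tp + tn + fp + fn
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what))
      return(NA_real_)
    }
    100 * num / den
  }
  list(accuracy = safe(tp + tn, n, "accuracy"),
       sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"))
}

#' F-beta score of sensitivity and specificity
#'
#' `(1 + beta^2) * Sens * Spec / (beta^2 * Sens + Spec)`. `beta < 1`
#' weights specificity (fall recall) more heavily; `beta = 0.5` is the
#' working default for fall detection. The score always lies between
#' `min(sens, spec)` and `max(sens, spec)` and equals both when they
#' agree.
#'
#' @param sensitivity,specificity rates on a common scale (percent or
#'   fraction; the score is scale-equivariant).
#' @param beta sensitivity/specificity trade-off weight, `> 0`.
#' @return the F-beta score on the input scale.
#' @export
f_score <- function(sensitivity, specificity, beta = 0.5) {
  num <- (1 + beta^2) * sensitivity * specificity
  den <- beta^2 * sensitivity + specificity
  ifelse(den == 0, 0, num / den)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive-class score outranks a
#' randomly chosen negative-class score, ties counting one half. Computed
#' by default from midranks (the normalized Mann-Whitney statistic);
#' `method = "trapezoid"` integrates the empirical ROC curve over all
#' score cut points instead -- the two are mathematically identical and
#' both are exposed as a cross-check.
#'
#' @param scores numeric scores; by convention the posterior of the class
#'   named by `positive`.
#' @param true_labels 0/1 labels.
#' @param positive the label whose scores should rank high (default 1).
#' @param method `"rank"` (default) or `"trapezoid"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, true_labels, positive = 1L,
                    method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  y <- as.integer(true_labels) == as.integer(positive)
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop_imbfall("both classes must be present to compute AUC",
                 "imbfall_value_error")
  if (method == "rank") {
    r <- rank(scores)               # midranks handle ties
    (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  } else {
    pts <- roc_points(scores, true_labels, positive)
    sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  }
}

#' Points of the empirical ROC curve
#'
#' One point per distinct score cut (plus the two trivial corners),
#' ordered from (0, 0) to (1, 1); suitable for plotting or CSV export.
#'
#' @inheritParams roc_auc
#' @return data frame with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, true_labels, positive = 1L) {
  y <- as.integer(true_labels) == as.integer(positive)
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) mean(scores[y] >= ct), 0)
  fpr <- vapply(cuts, function(ct) mean(scores[!y] >= ct), 0)
  data.frame(threshold = c(Inf, cuts),
             tpr = c(0, tpr), fpr = c(0, fpr))
}

#' Full evaluation report
#'
#' Confusion counts plus accuracy, sensitivity (ADL recall), specificity
#' (fall recall), F-beta and AUC, all as percentages.
#'
#' @param true_labels 0/1 labels (0 = ADL, 1 = fall).
#' @param pred_labels 0/1 predicted labels (e.g. from
#'   [apply_threshold()]).
#' @param scores optional minority (fall) posteriors for the AUC.
#' @param beta F-score weight (default 0.5).
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(true_labels, pred_labels, scores = NULL,
                        beta = 0.5) {
  cm <- confusion(true_labels, pred_labels)
  r <- rates(cm)
  auc <- if (!is.null(scores))
    100 * roc_auc(scores, true_labels, positive = 1L) else NA_real_
  structure(list(counts = cm, accuracy = r$accuracy,
                 sensitivity = r$sensitivity, specificity = r$specificity,
                 f_score = f_score(r$sensitivity, r$specificity, beta),
                 beta = beta, auc = auc,
                 n = sum(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report (positive = ADL, negative = fall)\n")
  cat(sprintf("  n = %d   TP %d  TN %d  FP %d  FN %d\n", x$n,
              x$counts[["tp"]], x$counts[["tn"]], x$counts[["fp"]],
              x$counts[["fn"]]))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("  accuracy %s  sensitivity %s  specificity (fall recall) %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("  F-%.1f %s  AUC %s\n", x$beta, fmt(x$f_score), fmt(x$auc)))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(tp = x$counts[["tp"]], tn = x$counts[["tn"]],
             fp = x$counts[["fp"]], fn = x$counts[["fn"]],
             accuracy = x$accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, f_score = x$f_score,
             beta = x$beta, auc = x$auc)
}
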