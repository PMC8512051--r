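# Output-threshold moving and the other class-imbalance strategies.
#
# A classifier trained on imbalanced data is biased toward the majority
# class: its minority posteriors rarely reach the conventional 0.5 cutoff
# even for true minority samples. Threshold moving leaves the trained
# model untouched and lowers the decision cutoff instead, either by
# matching the predicted minority fraction to the training-set minority
# frequency (empirical rule) or by a closed-form function of the
# imbalance ratio.

#' Decision-threshold policy
#'
#' Wraps the minority-class decision threshold `lambda` together with its
#' provenance: the conventional default `k` (0.5), an empirical match to
#' the training class distribution, or the closed-form map from the
#' imbalance ratio.
#'
#' @param lambda decision threshold in (0, 1); windows with minority
#'   (fall) posterior `>= lambda` are classified as falls.
#' @param k the default threshold the policy is relative to.
#' @param rho imbalance ratio the policy was derived from, if any.
#' @param provenance one of `"default"`, `"empirical"`, `"closed_form"`.
#' @return an object of class `threshold_policy`.
#' @export
threshold_policy <- function(lambda = 0.5, k = 0.5, rho = NA_real_,
                             provenance = "default") {
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop_imbfall("`lambda` must lie strictly inside (0, 1)",
                 "imbfall_value_error")
  structure(list(lambda = lambda, k = k, rho = rho,
                 provenance = provenance),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat(sprintf("<threshold_policy> lambda = %.4f (%s%s)\n", x$lambda,
              x$provenance,
              if (is.finite(x$rho)) sprintf(", rho = %.2f", x$rho) else ""))
  invisible(x)
}

#' Minority-class frequency of a training split
#'
#' @param x a `split_corpus` (its train split is used), a `window_set`,
#'   or an integer 0/1 label vector.
#' @return `n_minority / n_total` in `[0, 1]`, taking the fall class
#'   (label 1) as the minority.
#' @export
minority_frequency <- function(x) {
  y <- if (inherits(x, "split_corpus")) x$train$label
       else if (inherits(x, "window_set")) x$label
       else as.integer(x)
  if (length(y) == 0)
    stop_imbfall("empty training split", "imbfall_value_error")
  mean(y == 1L)
}

#' Empirical threshold matching the training class distribution
#'
#' Chooses the threshold `lambda` whose induced minority fraction
#' `f_lambda = mean(posterior >= lambda)` is closest to the training
#' minority frequency `f`, by exhaustive search over a finite candidate
#' grid; ties go to the smallest candidate. Evaluate it on validation
#' posteriors (not test) to avoid leakage.
#'
#' @param posteriors minority-class (fall) posterior probabilities: a
#'   numeric vector, or a posterior matrix whose `"fall"`/second column is
#'   used.
#' @param f target minority frequency in `[0, 1]` (see
#'   [minority_frequency()]).
#' @param grid candidate thresholds in (0, 1). Default: the sorted unique
#'   posterior values (clipped to (0,1)) united with 0.01..0.99 in steps
#'   of 0.01, so the search is exact yet finite.
#' @return a `threshold_policy` with provenance `"empirical"`.
#' @export
empirical_threshold <- function(posteriors, f, grid = NULL) {
  p <- .minority_posteriors(posteriors)
  if (length(p) == 0)
    stop_imbfall("empty posterior batch", "imbfall_value_error")
  if (is.null(grid))
    grid <- sort(unique(c(seq(0.01, 0.99, by = 0.01),
                          p[p > 0 & p < 1])))
  if (length(grid) == 0 || any(grid <= 0 | grid >= 1))
    stop_imbfall("`grid` must be non-empty with values in (0, 1)",
                 "imbfall_value_error")
  grid <- sort(grid)
  f_lambda <- vapply(grid, function(l) mean(p >= l), 0)
  obj <- abs(f - f_lambda)
  lam <- grid[which.min(obj)]   # which.min takes the first = smallest lambda
  threshold_policy(lam, k = NA_real_, rho = NA_real_,
                   provenance = "empirical")
}

#' Closed-form imbalance-ratio-to-threshold map
#'
#' `lambda* = k * exp(-rho / (10 k)) + k / 10`: a fitted decaying map
#' from the imbalance ratio `rho` to the decision threshold. It equals
#' about `k` for balanced data, decreases strictly in `rho`, and
#' approaches `k / 10` for extreme imbalance. At the reference corpus's
#' `rho = 11.23` (with `k = 0.5`) it gives 0.103, i.e. the working
#' threshold 0.1.
#'
#' @param rho imbalance ratio (majority / minority), `>= 0`.
#' @param k default threshold in (0, 1), usually 0.5.
#' @return a `threshold_policy` with provenance `"closed_form"`.
#' @examples
#' closed_form_threshold(11.23)$lambda   # 0.1029...
#' @export
closed_form_threshold <- function(rho, k = 0.5) {
  if (!is.finite(rho) || rho < 0)
    stop_imbfall("`rho` must be a non-negative finite number",
                 "imbfall_value_error")
  if (k <= 0 || k >= 1)
    stop_imbfall("`k` must lie strictly inside (0, 1)", "imbfall_value_error")
  lambda <- k * exp(-rho / (10 * k)) + k / 10
  threshold_policy(lambda, k = k, rho = rho, provenance = "closed_form")
}

#' Threshold posterior probabilities into binary decisions
#'
#' @param posteriors minority-class posteriors (vector or posterior
#'   matrix, see [empirical_threshold()]).
#' @param policy a [threshold_policy()].
#' @return integer vector, 1 (fall) where the minority posterior is
#'   `>= lambda`, else 0 (ADL); order-preserving.
#' @export
apply_threshold <- function(posteriors, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  p <- .minority_posteriors(posteriors)
  as.integer(p >= policy$lambda)
}

.minority_posteriors <- function(posteriors) {
  if (is.matrix(posteriors)) {
    j <- if (!is.null(colnames(posteriors)) &&
             "fall" %in% colnames(posteriors))
      which(colnames(posteriors) == "fall") else ncol(posteriors)
    posteriors <- posteriors[, j]
  }
  as.numeric(posteriors)
}

#' Inverse-frequency class weights for the training loss
#'
#' Weight of class `c` is `n_total / (2 * n_c)`, so weights average 1
#' over the training samples and the minority class is up-weighted by the
#' imbalance ratio.
#'
#' @param x a `split_corpus` (train split), `window_set`, or 0/1 label
#'   vector.
#' @return numeric length-2 vector `c(adl, fall)` of loss weights.
#' @export
class_weights <- function(x) {
  y <- if (inherits(x, "split_corpus")) x$train$label
       else if (inherits(x, "window_set")) x$label
       else as.integer(x)
  n <- tabulate(y + 1L, nbins = 2L)
  if (any(n == 0L))
    stop_imbfall("both classes must be present to compute class weights",
                 "imbfall_value_error")
  w <- length(y) / (2 * n)
  names(w) <- c("adl", "fall")
  w
}

#' Focal loss for a binary posterior
#'
#' `-alpha_t * (1 - p_t)^gamma * log(p_t)`, where `p_t` is the posterior
#' of the true class and `alpha_t` is `alpha` for the minority class
#' (label 1) and `1 - alpha` for the majority. `gamma = 0` reduces it to
#' (alpha-weighted) cross-entropy; well-classified samples
#' (`p_t` near 1) are down-weighted as `gamma` grows.
#'
#' @param posterior minority-class posterior `P(y = 1 | x)` in (0, 1)
#'   (vectorized).
#' @param true_label 0/1 labels.
#' @param gamma focusing exponent, `>= 0`.
#' @param alpha balance weight in (0, 1]; 0.5 weights both classes
#'   equally.
#' @return per-sample loss values.
#' @export
focal_loss <- function(posterior, true_label, gamma = 2, alpha = 0.5) {
  if (any(posterior <= 0 | posterior >= 1))
    stop_imbfall("`posterior` must lie strictly inside (0, 1)",
                 "imbfall_value_error")
  y <- as.integer(true_label)
  pt <- ifelse(y == 1L, posterior, 1 - posterior)
  at <- ifelse(y == 1L, alpha, 1 - alpha)
  -at * (1 - pt)^gamma * log(pt)
}
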