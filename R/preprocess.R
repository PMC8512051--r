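# Raw trials -> labeled fixed-length windows.
#
# Falls are first reduced to a 3 s segment centered on the SMV peak (the
# informative part of a fall recording: the long pre-fall activity is
# discarded); all trials are then cut into 1 s sliding windows that
# inherit the trial's binary label (0 = ADL, 1 = fall).

#' Signal magnitude vector (SMV)
#'
#' Euclidean norm of the tri-axial acceleration at each timestep,
#' `sqrt(ax^2 + ay^2 + az^2)`, in the unit of its inputs.
#'
#' @param ax,ay,az acceleration components (vectors of equal length), or
#'   pass a 3+ column matrix as `ax` (first three columns used).
#' @return non-negative numeric vector of magnitudes.
#' @export
smv <- function(ax, ay = NULL, az = NULL) {
  if (is.matrix(ax) && is.null(ay)) {
    ay <- ax[, 2]; az <- ax[, 3]; ax <- ax[, 1]
  }
  if (!all(is.finite(ax), is.finite(ay), is.finite(az)))
    stop_imbfall("non-finite acceleration input", "imbfall_value_error")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Per-trial maximum SMV and its position
#'
#' @param trial a `sensor_trial` (or a numeric matrix of samples x
#'   channels).
#' @return list with `value` (the maximum SMV) and `index` (1-based
#'   position of its first occurrence).
#' @export
smv_max <- function(trial) {
  data <- if (inherits(trial, "sensor_trial")) trial$data else trial
  if (is.null(dim(data)) || nrow(data) == 0)
    stop_imbfall("empty trial", "imbfall_value_error")
  s <- smv(data)
  i <- which.max(s)   # first occurrence on ties
  list(value = s[i], index = i)
}

#' Extract the peak-centered segment of a fall trial
#'
#' Returns a contiguous segment of `span_s` seconds centered on the
#' trial's SMV maximum. When the peak lies within half a span of either
#' edge the segment is shifted inward so that it always has full length;
#' it always contains the global SMV maximum.
#'
#' @param trial a `sensor_trial`.
#' @param span_s segment length in seconds (default 3).
#' @return a `sensor_trial` of exactly `round(span_s * fs)` samples.
#' @export
extract_fall_segment <- function(trial, span_s = 3) {
  stopifnot(inherits(trial, "sensor_trial"))
  n <- nrow(trial$data)
  w <- round(span_s * trial$fs)
  if (n < w)
    stop_imbfall(sprintf("trial has %d samples, shorter than the %d-sample segment",
                         n, w), "imbfall_value_error")
  peak <- smv_max(trial)$index
  start <- peak - w %/% 2                    # 1-based start
  start <- min(max(start, 1L), n - w + 1L)   # clip toward the interior
  seg <- trial$data[start:(start + w - 1L), , drop = FALSE]
  out <- trial
  out$data <- seg
  out$segment_start <- start
  out
}

#' Cut a trial into fixed-width sliding windows
#'
#' Windows start at offsets 0, stride, 2*stride, ... (samples); a trailing
#' partial window is dropped, so the count is
#' `floor((L - W) / S) + 1` for trial length `L`, window width `W` and
#' stride `S` in samples. Every window inherits the trial's binary label.
#'
#' @param trial a `sensor_trial`.
#' @param width_s window width in seconds (default 1).
#' @param stride_s hop between window starts in seconds (default 0.5, i.e.
#'   50\% overlap).
#' @return a `window_set` (see [window_corpus()]).
#' @export
sliding_windows <- function(trial, width_s = 1, stride_s = 0.5) {
  stopifnot(inherits(trial, "sensor_trial"))
  assert_scalar_pos(stride_s, "stride_s", "imbfall_value_error")
  L <- nrow(trial$data)
  W <- round(width_s * trial$fs)
  S <- max(1L, round(stride_s * trial$fs))
  if (W > L)
    stop_imbfall(sprintf("window (%d samples) wider than trial (%d samples)",
                         W, L), "imbfall_value_error")
  n_win <- (L - W) %/% S + 1L
  offsets <- (seq_len(n_win) - 1L) * S       # 0-based starts
  C <- ncol(trial$data)
  x <- array(0, c(n_win, W, C))
  for (i in seq_len(n_win))
    x[i, , ] <- trial$data[(offsets[i] + 1L):(offsets[i] + W), ]
  new_window_set(x,
                 label = rep(as.integer(trial$is_fall), n_win),
                 trial_id = rep(trial$trial_id, n_win),
                 offset = offsets, fs = trial$fs, width_s = width_s)
}

new_window_set <- function(x, label, trial_id, offset, fs, width_s) {
  structure(list(x = x, label = as.integer(label), trial_id = trial_id,
                 offset = as.integer(offset), fs = fs, width_s = width_s),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x %d channels (%d ADL, %d fall)\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3],
              sum(x$label == 0L), sum(x$label == 1L)))
  invisible(x)
}

#' @export
length.window_set <- function(x) dim(x$x)[1]

subset_windows <- function(ws, idx) {
  new_window_set(ws$x[idx, , , drop = FALSE], ws$label[idx],
                 ws$trial_id[idx], ws$offset[idx], ws$fs, ws$width_s)
}

bind_windows <- function(a, b) {
  stopifnot(dim(a$x)[2] == dim(b$x)[2], dim(a$x)[3] == dim(b$x)[3])
  x <- array(0, c(dim(a$x)[1] + dim(b$x)[1], dim(a$x)[2], dim(a$x)[3]))
  x[seq_len(dim(a$x)[1]), , ] <- a$x
  x[dim(a$x)[1] + seq_len(dim(b$x)[1]), , ] <- b$x
  new_window_set(x, c(a$label, b$label), c(a$trial_id, b$trial_id),
                 c(a$offset, b$offset), a$fs, a$width_s)
}

#' Window a whole corpus
#'
#' ADL trials are windowed over their full length; fall trials are first
#' reduced to the `fall_span_s` peak-centered segment (the fall signature)
#' and then windowed, so each fall trial contributes only windows around
#' its impact.
#'
#' @param corpus a `trial_corpus`.
#' @param width_s,stride_s window width and stride, seconds.
#' @param fall_span_s span of the peak-centered fall segment, seconds.
#' @return a `window_set`: list with `x` (array `n x W x C`), `label`
#'   (integer, 0 = ADL / 1 = fall), `trial_id`, `offset` (0-based start
#'   within the windowed trial/segment), `fs`, `width_s`.
#' @export
window_corpus <- function(corpus, width_s = 1, stride_s = 0.5,
                          fall_span_s = 3) {
  stopifnot(inherits(corpus, "trial_corpus"))
  parts <- lapply(corpus$trials, function(tr) {
    if (tr$is_fall) tr <- extract_fall_segment(tr, fall_span_s)
    sliding_windows(tr, width_s, stride_s)
  })
  Reduce(bind_windows, parts)
}

#' Class imbalance ratio
#'
#' The number of majority-class samples divided by the number of
#' minority-class samples. The caller passes the majority count first;
#' the function does not reorder its arguments.
#'
#' @param n_majority,n_minority class counts.
#' @return `n_majority / n_minority`.
#' @examples
#' imbalance_ratio(94786, 8439)  # 11.23, the reference corpus
#' @export
imbalance_ratio <- function(n_majority, n_minority) {
  if (n_minority <= 0)
    stop_imbfall("minority count must be positive", "imbfall_value_error")
  if (n_majority < 0)
    stop_imbfall("majority count must be non-negative", "imbfall_value_error")
  n_majority / n_minority
}

#' Split windows into train / validation / test sets
#'
#' Random, label-stratified partition in the given ratio (default 6:2:2).
#' Stratification keeps the minority proportion of each split within one
#' window of the corpus proportion, which matters at high imbalance where
#' a plain random cut can leave a split with no falls at all.
#'
#' @param windows a `window_set`.
#' @param ratio length-3 positive weights for train/validation/test.
#' @param seed integer seed for the shuffle.
#' @return an object of class `split_corpus`: list with `train`,
#'   `validation`, `test` (`window_set`s), `counts` (2 x 3 class-count
#'   matrix), `ratio` and `seed`.
#' @export
split_corpus <- function(windows, ratio = c(6, 2, 2), seed = 0L) {
  stopifnot(inherits(windows, "window_set"))
  if (length(ratio) != 3 || any(!is.finite(ratio)) || any(ratio <= 0))
    stop_imbfall("`ratio` must be three positive numbers", "imbfall_value_error")
  n <- length(windows)
  frac <- cumsum(ratio) / sum(ratio)
  idx_split <- vector("list", 3)
  with_seed(seed, {
    for (lab in sort(unique(windows$label))) {
      idx <- which(windows$label == lab)
      idx <- sample(idx)
      cuts <- round(frac * length(idx))
      starts <- c(0L, cuts[1:2]) + 1L
      for (s in 1:3) {
        take <- if (starts[s] <= cuts[s]) idx[starts[s]:cuts[s]] else integer(0)
        idx_split[[s]] <- c(idx_split[[s]], take)
      }
    }
    # re-shuffle within each split so classes are interleaved
    idx_split <- lapply(idx_split, sample)
  })
  sets <- lapply(idx_split, function(i) subset_windows(windows, i))
  names(sets) <- c("train", "validation", "test")
  counts <- vapply(sets, function(s)
    c(adl = sum(s$label == 0L), fall = sum(s$label == 1L)), numeric(2))
  structure(c(sets, list(counts = counts, ratio = ratio, seed = seed)),
            class = "split_corpus")
}

#' @export
print.split_corpus <- function(x, ...) {
  cat("<split_corpus>\n")
  print(x$counts)
  f <- minority_frequency(x)
  cat(sprintf("train minority frequency f = %.4f, imbalance ratio = %.2f\n",
              f, (1 - f) / f))
  invisible(x)
}
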