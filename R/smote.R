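#' SMOTE oversampling of minority windows
#'
#' Synthetic Minority Over-sampling: each synthetic window is drawn on
#' the straight line between a real minority window `x` and one of its
#' `k_neighbors` nearest minority neighbours `x_nn` (Euclidean distance on
#' the flattened window), `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`.
#' Apply it to the training split only; oversampling validation or test
#' data leaks information.
#'
#' @param minority_windows a `window_set` containing only minority (fall)
#'   windows, or an array `(n, timesteps, channels)`.
#' @param n_new number of synthetic windows to generate.
#' @param k_neighbors neighbourhood size (must be smaller than the
#'   minority count).
#' @param seed integer seed.
#' @return a `window_set` of `n_new` synthetic windows labeled 1, with
#'   trial ids `"smote_<i>"`.
#' @export
smote_windows <- function(minority_windows, n_new, k_neighbors = 5,
                          seed = 0L) {
  ws <- minority_windows
  if (inherits(ws, "window_set")) {
    x <- ws$x; fs <- ws$fs; width_s <- ws$width_s
  } else {
    x <- ws; fs <- NA_real_; width_s <- NA_real_
  }
  n <- dim(x)[1]
  if (n <= k_neighbors)
    stop_imbfall(sprintf("need more than k_neighbors = %d minority windows, got %d",
                         k_neighbors, n), "imbfall_value_error")
  W <- dim(x)[2]; C <- dim(x)[3]
  if (n_new == 0)
    return(new_window_set(array(0, c(0L, W, C)), integer(0), character(0),
                          integer(0), fs, width_s))
  flat <- matrix(x, n, W * C)
  # exact k-nearest-neighbour table on the flattened windows
  d2 <- as.matrix(stats::dist(flat))^2
  diag(d2) <- Inf
  nn <- matrix(0L, n, k_neighbors)
  for (i in seq_len(n)) nn[i, ] <- order(d2[i, ])[seq_len(k_neighbors)]
  out <- array(0, c(n_new, W, C))
  with_seed(seed, {
    base <- (seq_len(n_new) - 1L) %% n + 1L   # cycle through real windows
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    for (i in seq_len(n_new)) {
      v <- flat[base[i], ] + u[i] * (flat[pick[i], ] - flat[base[i], ])
      out[i, , ] <- array(v, c(W, C))
    }
  })
  new_window_set(out, rep(1L, n_new),
                 sprintf("smote_%04d", seq_len(n_new)),
                 rep(-1L, n_new), fs, width_s)
}
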