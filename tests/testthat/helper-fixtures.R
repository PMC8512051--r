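# Small shared fixtures, built in code at test time.

# a tiny but complete corpus: enough windows per class for training tests
# while keeping every test file fast
tiny_corpus <- function(n_adl = 24, n_fall = 8, master_seed = 11) {
  sim_corpus(sim_config(n_adl = n_adl, n_fall = n_fall,
                        master_seed = master_seed))
}

tiny_split <- function(..., seed = 5) {
  split_corpus(window_corpus(tiny_corpus(...)), seed = seed)
}

# a trial with a hand-set SMV trace: channels (x, 0, 0) so SMV == |x|
trace_trial <- function(xs, fs = 200, is_fall = FALSE) {
  imbfall:::new_sensor_trial(cbind(xs, 0, 0), fs, "synthetic", is_fall,
                             "trace", 0L)
}

# brute-force 1x-K cross-correlation with zero padding (independent oracle
# for the vectorized convolution)
conv1d_loops <- function(x, W, b, stride = 1L) {
  d <- dim(x); N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  p <- (K - 1L) %/% 2L
  Lout <- (L + 2L * p - K) %/% stride + 1L
  y <- array(0, c(N, Lout, Cout))
  for (n in seq_len(N)) for (t in seq_len(Lout)) for (co in seq_len(Cout)) {
    acc <- b[co]
    for (k in seq_len(K)) for (ci in seq_len(Cin)) {
      src <- (t - 1L) * stride + k - p   # position in the unpadded input
      if (src >= 1L && src <= L) acc <- acc + x[n, src, ci] * W[k, ci, co]
    }
    y[n, t, co] <- acc
  }
  y
}

# pairwise-rank AUC oracle: enumerate all positive/negative pairs
auc_pairs <- function(scores, labels, positive = 1L) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
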