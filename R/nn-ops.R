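# Low-level differentiable ops for the 1D residual network.
#
# No deep-learning framework is assumed: convolutions are expressed as
# matrix products over kernel taps (three taps for the 1x3 kernels used
# throughout), which hands the work to BLAS. Batch tensors are dense
# arrays of dim (batch, time, channels); pointwise ops reshape them to a
# (batch*time) x channels matrix.

# -- 1D convolution (zero "same" padding, optional stride) ------------------

conv1d_fwd <- function(x, W, b, stride = 1L) {
  d <- dim(x); N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  p <- (K - 1L) %/% 2L
  Lp <- L + 2L * p
  xpad <- array(0, c(N, Lp, Cin))
  xpad[, (p + 1L):(p + L), ] <- x
  Lout <- (Lp - K) %/% stride + 1L
  y <- matrix(b, N * Lout, Cout, byrow = TRUE)
  Xk <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- seq.int(k, by = stride, length.out = Lout)
    Xk[[k]] <- matrix(xpad[, idx, , drop = FALSE], N * Lout, Cin)
    y <- y + Xk[[k]] %*% matrix(W[k, , ], Cin, Cout)
  }
  list(y = array(y, c(N, Lout, Cout)),
       cache = list(Xk = Xk, dimx = d, stride = stride, K = K, p = p,
                    Lout = Lout))
}

conv1d_bwd <- function(dy, W, cache) {
  d <- cache$dimx; N <- d[1]; L <- d[2]; Cin <- d[3]
  K <- cache$K; p <- cache$p; Lout <- cache$Lout
  Cout <- dim(W)[3]
  D <- matrix(dy, N * Lout, Cout)
  dW <- array(0, dim(W))
  dxpad <- array(0, c(N, L + 2L * p, Cin))
  for (k in seq_len(K)) {
    dW[k, , ] <- crossprod(cache$Xk[[k]], D)
    dXk <- array(tcrossprod(D, matrix(W[k, , ], Cin, Cout)),
                 c(N, Lout, Cin))
    idx <- seq.int(k, by = cache$stride, length.out = Lout)
    dxpad[, idx, ] <- dxpad[, idx, ] + dXk
  }
  list(dx = dxpad[, (p + 1L):(p + L), , drop = FALSE],
       dW = dW, db = colSums(D))
}

# -- batch normalization over (batch, time) per channel ---------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(x, gamma, beta, running, training) {
  d <- dim(x); M <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, M, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - matrix(mu, M, C, byrow = TRUE)
    v <- colMeans(xc * xc)                  # biased batch variance
    running$mean <- (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu
    running$var <- (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- xm - matrix(mu, M, C, byrow = TRUE)
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * matrix(inv_sd, M, C, byrow = TRUE)
  y <- xhat * matrix(gamma, M, C, byrow = TRUE) +
    matrix(beta, M, C, byrow = TRUE)
  list(y = array(y, d), running = running,
       cache = list(xhat = xhat, inv_sd = inv_sd, dimx = d))
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$dimx; M <- d[1] * d[2]; C <- d[3]
  dym <- matrix(dy, M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  # fused batch-norm gradient (biased-variance convention)
  coef <- matrix(gamma * cache$inv_sd / M, M, C, byrow = TRUE)
  dx <- coef * (M * dym -
                  matrix(dbeta, M, C, byrow = TRUE) -
                  xhat * matrix(dgamma, M, C, byrow = TRUE))
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# -- pointwise / pooling / dense --------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(dy, mask) dy * mask

gap_fwd <- function(x) {
  d <- dim(x)   # (N, L, C)
  m <- colSums(matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])) / d[2]
  list(y = matrix(m, d[1], d[3]), dimx = d)
}

gap_bwd <- function(dy, dimx) {
  aperm(array(dy / dimx[2], c(dimx[1], dimx[3], dimx[2])), c(1, 3, 2))
}

dense_fwd <- function(x, W, b) {
  list(y = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE), x = x)
}

dense_bwd <- function(dy, W, cache) {
  list(dx = tcrossprod(dy, W), dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# -- losses on softmax outputs ----------------------------------------------
# All return the scalar mean loss over the batch and the gradient w.r.t.
# the logits. `y` is the 0/1 class index (col 1 = class 0, col 2 = class 1).

loss_ce <- function(p, y, sample_w = NULL) {
  n <- nrow(p)
  if (is.null(sample_w)) sample_w <- rep(1, n)
  it <- cbind(seq_len(n), y + 1L)
  pt <- pmax(p[it], 1e-12)
  loss <- mean(sample_w * (-log(pt)))
  onehot <- matrix(0, n, ncol(p))
  onehot[it] <- 1
  dlogits <- (p - onehot) * (sample_w / n)
  list(loss = loss, dlogits = dlogits)
}

loss_focal <- function(p, y, gamma = 2, alpha = 0.5) {
  n <- nrow(p)
  it <- cbind(seq_len(n), y + 1L)
  pt <- pmin(pmax(p[it], 1e-12), 1 - 1e-12)
  at <- ifelse(y == 1L, alpha, 1 - alpha)
  loss <- mean(-at * (1 - pt)^gamma * log(pt))
  # dL/dp_t, then through the softmax Jacobian:
  # dL/dz_j = dL/dp_t * p_t * (delta_tj - p_j)
  dpt <- at * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  onehot <- matrix(0, n, ncol(p))
  onehot[it] <- 1
  list(loss = loss, dlogits = (dpt * pt / n) * (onehot - p))
}
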