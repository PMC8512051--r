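# Network assembly, forward/backward pass and the Adam training loop for
# the small 1D residual network ("ResNet10"-class: four residual blocks of
# two 1x3 convolutions each, batch norm and ReLU throughout, shortcut
# additions, global average pooling and a softmax head).

net_arch <- function(in_channels, channels, kernel_width) {
  blocks <- vector("list", length(channels))
  cin <- in_channels
  for (i in seq_along(channels)) {
    cout <- channels[i]
    stride <- 2L                      # downsample at each block boundary
    blocks[[i]] <- list(cin = cin, cout = cout, stride = stride,
                        proj = (cin != cout || stride != 1L),
                        K = kernel_width)
    cin <- cout
  }
  blocks
}

net_init <- function(arch, n_classes, seed) {
  params <- list()
  running <- list()
  with_seed(seed, {
    he <- function(K, cin, cout)
      array(stats::rnorm(K * cin * cout, 0, sqrt(2 / (K * cin))),
            c(K, cin, cout))
    for (i in seq_along(arch)) {
      s <- arch[[i]]
      pre <- sprintf("b%d.", i)
      params[[paste0(pre, "conv1.W")]] <- he(s$K, s$cin, s$cout)
      params[[paste0(pre, "conv1.b")]] <- numeric(s$cout)
      params[[paste0(pre, "bn1.gamma")]] <- rep(1, s$cout)
      params[[paste0(pre, "bn1.beta")]] <- numeric(s$cout)
      params[[paste0(pre, "conv2.W")]] <- he(s$K, s$cout, s$cout)
      params[[paste0(pre, "conv2.b")]] <- numeric(s$cout)
      params[[paste0(pre, "bn2.gamma")]] <- rep(1, s$cout)
      params[[paste0(pre, "bn2.beta")]] <- numeric(s$cout)
      running[[paste0(pre, "bn1")]] <- list(mean = numeric(s$cout),
                                            var = rep(1, s$cout))
      running[[paste0(pre, "bn2")]] <- list(mean = numeric(s$cout),
                                            var = rep(1, s$cout))
      if (s$proj) {
        params[[paste0(pre, "proj.W")]] <- he(1L, s$cin, s$cout)
        params[[paste0(pre, "proj.b")]] <- numeric(s$cout)
        params[[paste0(pre, "bnp.gamma")]] <- rep(1, s$cout)
        params[[paste0(pre, "bnp.beta")]] <- numeric(s$cout)
        running[[paste0(pre, "bnp")]] <- list(mean = numeric(s$cout),
                                              var = rep(1, s$cout))
      }
    }
    clast <- arch[[length(arch)]]$cout
    params[["head.W"]] <- matrix(stats::rnorm(clast * n_classes, 0,
                                              sqrt(2 / clast)),
                                 clast, n_classes)
    params[["head.b"]] <- numeric(n_classes)
  })
  list(params = params, running = running)
}

# One residual block: conv -> BN -> ReLU -> conv -> BN, added to the
# (possibly projected) shortcut, then ReLU. Zero residual weights reduce
# the block to a ReLU identity.
block_fwd <- function(x, i, spec, params, running, training) {
  pre <- sprintf("b%d.", i)
  c1 <- conv1d_fwd(x, params[[paste0(pre, "conv1.W")]],
                   params[[paste0(pre, "conv1.b")]], spec$stride)
  n1 <- bn_fwd(c1$y, params[[paste0(pre, "bn1.gamma")]],
               params[[paste0(pre, "bn1.beta")]],
               running[[paste0(pre, "bn1")]], training)
  running[[paste0(pre, "bn1")]] <- n1$running
  r1 <- relu_fwd(n1$y)
  c2 <- conv1d_fwd(r1$y, params[[paste0(pre, "conv2.W")]],
                   params[[paste0(pre, "conv2.b")]], 1L)
  n2 <- bn_fwd(c2$y, params[[paste0(pre, "bn2.gamma")]],
               params[[paste0(pre, "bn2.beta")]],
               running[[paste0(pre, "bn2")]], training)
  running[[paste0(pre, "bn2")]] <- n2$running
  if (spec$proj) {
    cp <- conv1d_fwd(x, params[[paste0(pre, "proj.W")]],
                     params[[paste0(pre, "proj.b")]], spec$stride)
    np <- bn_fwd(cp$y, params[[paste0(pre, "bnp.gamma")]],
                 params[[paste0(pre, "bnp.beta")]],
                 running[[paste0(pre, "bnp")]], training)
    running[[paste0(pre, "bnp")]] <- np$running
    sc <- np$y
  } else {
    cp <- np <- NULL
    sc <- x
  }
  r2 <- relu_fwd(n2$y + sc)
  list(y = r2$y, running = running,
       cache = list(c1 = c1$cache, n1 = n1$cache, r1 = r1$mask,
                    c2 = c2$cache, n2 = n2$cache,
                    cp = if (spec$proj) cp$cache else NULL,
                    np = if (spec$proj) np$cache else NULL,
                    r2 = r2$mask))
}

block_bwd <- function(dy, i, spec, params, cache, grads) {
  pre <- sprintf("b%d.", i)
  dsum <- relu_bwd(dy, cache$r2)
  # main branch
  g2 <- bn_bwd(dsum, params[[paste0(pre, "bn2.gamma")]], cache$n2)
  grads[[paste0(pre, "bn2.gamma")]] <- g2$dgamma
  grads[[paste0(pre, "bn2.beta")]] <- g2$dbeta
  k2 <- conv1d_bwd(g2$dx, params[[paste0(pre, "conv2.W")]], cache$c2)
  grads[[paste0(pre, "conv2.W")]] <- k2$dW
  grads[[paste0(pre, "conv2.b")]] <- k2$db
  dr1 <- relu_bwd(k2$dx, cache$r1)
  g1 <- bn_bwd(dr1, params[[paste0(pre, "bn1.gamma")]], cache$n1)
  grads[[paste0(pre, "bn1.gamma")]] <- g1$dgamma
  grads[[paste0(pre, "bn1.beta")]] <- g1$dbeta
  k1 <- conv1d_bwd(g1$dx, params[[paste0(pre, "conv1.W")]], cache$c1)
  grads[[paste0(pre, "conv1.W")]] <- k1$dW
  grads[[paste0(pre, "conv1.b")]] <- k1$db
  dx <- k1$dx
  # shortcut branch
  if (spec$proj) {
    gp <- bn_bwd(dsum, params[[paste0(pre, "bnp.gamma")]], cache$np)
    grads[[paste0(pre, "bnp.gamma")]] <- gp$dgamma
    grads[[paste0(pre, "bnp.beta")]] <- gp$dbeta
    kp <- conv1d_bwd(gp$dx, params[[paste0(pre, "proj.W")]], cache$cp)
    grads[[paste0(pre, "proj.W")]] <- kp$dW
    grads[[paste0(pre, "proj.b")]] <- kp$db
    dx <- dx + kp$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

net_fwd <- function(x, params, arch, running, training) {
  caches <- vector("list", length(arch))
  h <- x
  for (i in seq_along(arch)) {
    out <- block_fwd(h, i, arch[[i]], params, running, training)
    h <- out$y
    running <- out$running
    caches[[i]] <- out$cache
  }
  g <- gap_fwd(h)
  d <- dense_fwd(g$y, params[["head.W"]], params[["head.b"]])
  list(logits = d$y, p = softmax(d$y), running = running,
       caches = list(blocks = caches, gap = g$dimx, dense = d))
}

net_bwd <- function(dlogits, params, arch, caches) {
  grads <- list()
  db <- dense_bwd(dlogits, params[["head.W"]], caches$dense)
  grads[["head.W"]] <- db$dW
  grads[["head.b"]] <- db$db
  dh <- gap_bwd(db$dx, caches$gap)
  for (i in rev(seq_along(arch))) {
    out <- block_bwd(dh, i, arch[[i]], params, caches$blocks[[i]], grads)
    dh <- out$dx
    grads <- out$grads
  }
  grads
}

# posterior probabilities in eval mode (running BN statistics), chunked to
# bound memory on large window sets
net_predict <- function(x, params, arch, running, chunk = 512L) {
  n <- dim(x)[1]
  if (n == 0L)
    return(matrix(numeric(0), 0, ncol(params[["head.W"]])))
  out <- matrix(0, n, ncol(params[["head.W"]]))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- net_fwd(x[i:j, , , drop = FALSE], params, arch, running,
                          training = FALSE)$p
    i <- j + 1L
  }
  out
}

batch_loss <- function(p, y, loss_spec) {
  if (loss_spec$type == "focal") {
    loss_focal(p, y, loss_spec$gamma, loss_spec$alpha)
  } else {
    sw <- if (!is.null(loss_spec$weights)) loss_spec$weights[y + 1L] else NULL
    loss_ce(p, y, sw)
  }
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Full training loop: mini-batch Adam with per-epoch validation, returning
# the parameter set (and BN statistics) of the best-validation-loss epoch.
train_network <- function(x_train, y_train, x_val, y_val, config, loss_spec) {
  arch <- net_arch(dim(x_train)[3], config$channels, config$kernel_width)
  init <- net_init(arch, config$n_classes, config$seed)
  params <- init$params
  running <- init$running
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- dim(x_train)[1]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_accuracy = numeric(0))
  best <- list(val_loss = Inf, params = params, running = running,
               epoch = 0L)
  with_seed(derive_seed(config$seed, 97L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      n_batches <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        idx <- ord[i:j]
        fw <- net_fwd(x_train[idx, , , drop = FALSE], params, arch, running,
                      training = TRUE)
        running <- fw$running
        lo <- batch_loss(fw$p, y_train[idx], loss_spec)
        grads <- net_bwd(lo$dlogits, params, arch, fw$caches)
        up <- adam_step(params, grads, state, config$learning_rate)
        params <- up$params
        state <- up$state
        ep_loss <- ep_loss + lo$loss
        n_batches <- n_batches + 1L
        i <- j + 1L
      }
      pv <- net_predict(x_val, params, arch, running)
      vl <- batch_loss(pv, y_val, loss_spec)$loss
      vacc <- mean((pv[, 2] >= 0.5) == (y_val == 1L))
      history[epoch, ] <- list(epoch, ep_loss / n_batches, vl, vacc)
      if (vl < best$val_loss) {
        best <- list(val_loss = vl, params = params, running = running,
                     epoch = epoch)
      }
    }
  })
  list(params = best$params, running = best$running,
       arch = arch, history = history, best_epoch = best$epoch,
       best_val_loss = best$val_loss)
}
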