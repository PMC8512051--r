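test_that("the 1x3 convolution matches a brute-force triple-loop oracle", {
  set.seed(31)
  for (i in 1:12) {
    N <- sample(1:3, 1); L <- sample(4:9, 1)
    Cin <- sample(1:3, 1); Cout <- sample(1:4, 1)
    stride <- sample(1:2, 1)
    x <- array(rnorm(N * L * Cin), c(N, L, Cin))
    W <- array(rnorm(3 * Cin * Cout), c(3, Cin, Cout))
    b <- rnorm(Cout)
    got <- imbfall:::conv1d_fwd(x, W, b, stride)$y
    expect_equal(got, conv1d_loops(x, W, b, stride), tolerance = 1e-12)
  }
})

test_that("a single-timestep toy input reproduces the hand-computed convolution", {
  # one sample, three timesteps, one channel; kernel (w1, w2, w3), bias b:
  # with zero padding, output t=2 is w1*x1 + w2*x2 + w3*x3 + b
  x <- array(c(1, 2, 3), c(1, 3, 1))
  W <- array(c(0.5, -1, 2), c(3, 1, 1))
  b <- 0.25
  y <- imbfall:::conv1d_fwd(x, W, b, 1L)$y
  expect_equal(as.numeric(y),
               c(-1 * 1 + 2 * 2 + 0.25,        # t=1 (left zero pad)
                 0.5 * 1 - 1 * 2 + 2 * 3 + 0.25,
                 0.5 * 2 - 1 * 3 + 0.25))      # t=3 (right zero pad)
})

test_that("a zero residual branch reduces the block to a ReLU identity", {
  spec <- list(cin = 4, cout = 4, stride = 1L, proj = FALSE, K = 3L)
  init <- imbfall:::net_init(list(spec), 2L, seed = 1)
  params <- init$params
  # zero out the residual branch F(x); keep BN at identity scale
  for (nm in c("b1.conv1.W", "b1.conv1.b", "b1.conv2.W", "b1.conv2.b"))
    params[[nm]] <- params[[nm]] * 0
  x <- array(rnorm(2 * 6 * 4), c(2, 6, 4))
  out <- imbfall:::block_fwd(x, 1L, spec, params, init$running,
                             training = TRUE)
  expect_equal(out$y, x * (x > 0), tolerance = 1e-6)
})

test_that("residual blocks preserve shape (identity) or project it (channel change)", {
  id_spec <- list(cin = 8, cout = 8, stride = 1L, proj = FALSE, K = 3L)
  init <- imbfall:::net_init(list(id_spec), 2L, seed = 2)
  x <- array(rnorm(3 * 10 * 8), c(3, 10, 8))
  out <- imbfall:::block_fwd(x, 1L, id_spec, init$params, init$running, TRUE)
  expect_equal(dim(out$y), dim(x))

  pr_spec <- list(cin = 8, cout = 16, stride = 2L, proj = TRUE, K = 3L)
  init2 <- imbfall:::net_init(list(pr_spec), 2L, seed = 2)
  out2 <- imbfall:::block_fwd(x, 1L, pr_spec, init2$params, init2$running, TRUE)
  expect_equal(dim(out2$y), c(3, 5, 16))
})

test_that("softmax outputs normalize to one and are symmetric at zero logits", {
  expect_equal(as.numeric(imbfall:::softmax(matrix(c(0, 0), 1))),
               c(0.5, 0.5))
  set.seed(7)
  z <- matrix(rnorm(200 * 2, sd = 5), 200)
  p <- imbfall:::softmax(z)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 200), tolerance = 1e-12)
  # invariant under per-row shifts
  expect_equal(imbfall:::softmax(z + 3), p, tolerance = 1e-12)
})

test_that("network construction is deterministic given the seed", {
  cfg <- net_config(channels = c(4, 8), seed = 42)
  arch <- imbfall:::net_arch(3L, cfg$channels, cfg$kernel_width)
  a <- imbfall:::net_init(arch, 2L, cfg$seed)
  b <- imbfall:::net_init(arch, 2L, cfg$seed)
  expect_identical(a$params, b$params)
  c <- imbfall:::net_init(arch, 2L, 43L)
  expect_false(identical(a$params, c$params))
})

test_that("forward passes give probability rows summing to one for any batch", {
  cfg <- net_config(channels = c(4, 8), seed = 1)
  arch <- imbfall:::net_arch(3L, cfg$channels, cfg$kernel_width)
  init <- imbfall:::net_init(arch, 2L, 1L)
  x <- array(rnorm(40 * 32 * 3), c(40, 32, 3))
  p <- imbfall:::net_predict(x, init$params, arch, init$running)
  expect_equal(dim(p), c(40, 2))
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  # empty input -> empty batch
  p0 <- imbfall:::net_predict(x[0, , , drop = FALSE], init$params, arch,
                              init$running)
  expect_equal(nrow(p0), 0)
})

test_that("training on a separable corpus reaches high validation accuracy and is reproducible", {
  split <- tiny_split(n_adl = 24, n_fall = 8, master_seed = 11, seed = 5)
  cfg <- net_config(channels = c(8, 16), max_epochs = 4, batch_size = 32,
                    seed = 3)
  fit <- fall_resnet(split, config = cfg)
  expect_s3_class(fit, "fall_resnet")
  expect_gt(max(fit$history$val_accuracy), 0.95)
  # checkpoint-selection contract: returned epoch is no worse than epoch 1
  expect_lte(fit$best_val_loss, fit$history$val_loss[1])

  fit2 <- fall_resnet(split, config = cfg)
  expect_equal(fit$history, fit2$history, tolerance = 1e-12)
  expect_equal(fit$params, fit2$params, tolerance = 1e-12)
})

test_that("predictions are order-preserving, pure and shape-checked", {
  split <- tiny_split(n_adl = 24, n_fall = 8, master_seed = 11, seed = 5)
  cfg <- net_config(channels = c(8, 16), max_epochs = 1, batch_size = 32,
                    seed = 3)
  fit <- fall_resnet(split, config = cfg)
  p <- predict(fit, split$test)
  expect_equal(colnames(p), c("adl", "fall"))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)

  # duplicated window -> identical rows; order preserved
  x2 <- split$test$x[c(1, 1, 2), , , drop = FALSE]
  p2 <- predict(fit, x2)
  expect_equal(p2[1, ], p2[2, ])
  expect_equal(p2[3, ], p[2, ])

  bad <- array(0, c(2, 10, 3))
  expect_error(predict(fit, bad), class = "imbfall_shape_error")
})

test_that("fitted-model methods print, summarise and expose coefficients", {
  split <- tiny_split(n_adl = 24, n_fall = 8, master_seed = 11, seed = 5)
  fit <- fall_resnet(split, config = net_config(channels = c(4, 8),
                                                max_epochs = 1, seed = 3))
  expect_output(print(fit), "residual-network fall classifier")
  s <- summary(fit)
  expect_gt(s$n_parameters, 100)
  expect_output(print(s), "trainable parameters")
  expect_true("head.W" %in% names(coef(fit)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
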