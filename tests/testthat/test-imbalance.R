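test_that("minority frequency is the fall fraction of the training split", {
  expect_equal(minority_frequency(c(rep(0L, 90), rep(1L, 10))), 0.1)
  expect_equal(minority_frequency(c(rep(0L, 50), rep(1L, 50))), 0.5)
  # the reference corpus accounting: 8439 falls among 103225 windows
  expect_equal(round(minority_frequency(c(rep(0L, 94786), rep(1L, 8439))), 4),
               0.0818)
  expect_error(minority_frequency(integer(0)), class = "imbfall_value_error")
})

test_that("the empirical threshold matches the class distribution on the worked grid", {
  p <- c(0.9, 0.8, 0.3, 0.2, 0.1)
  # explicit literals: seq() would produce 0.30000000000000004 and silently
  # exclude the posterior exactly at 0.3 from its own cutoff
  grid10 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  pol <- empirical_threshold(p, f = 0.4, grid = grid10)
  expect_equal(pol$lambda, 0.4)   # f_lambda = 0.4 for 0.4..0.8; smallest wins
  expect_equal(pol$provenance, "empirical")

  # f = 1: everything minority -> smallest grid value
  pol2 <- empirical_threshold(p, f = 1, grid = grid10)
  expect_equal(pol2$lambda, 0.1)

  expect_error(empirical_threshold(numeric(0), 0.5),
               class = "imbfall_value_error")
  expect_error(empirical_threshold(p, 0.5, grid = c(0, 0.5)),
               class = "imbfall_value_error")
})

test_that("the empirical threshold is the exhaustive-search argmin on random batches", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    p <- runif(n)
    f <- runif(1)
    grid <- sort(unique(c(seq(0.01, 0.99, by = 0.01), p[p > 0 & p < 1])))
    pol <- empirical_threshold(p, f)
    # brute force over the same default grid
    obj <- vapply(grid, function(l) abs(f - mean(p >= l)), 0)
    best <- min(obj)
    expect_equal(abs(f - mean(p >= pol$lambda)), best, tolerance = 1e-12)
    # ties resolved to the smallest candidate
    expect_equal(pol$lambda, grid[which(obj <= best + 1e-12)[1]])
    # argmin definition holds pointwise
    expect_true(all(abs(f - mean(p >= pol$lambda)) <= obj + 1e-12))
  }
})

test_that("on posteriors whose induced fraction can match f exactly, the gap is zero", {
  set.seed(5)
  p <- runif(40)
  f <- mean(p >= sort(p)[15])      # attainable fraction by construction
  pol <- empirical_threshold(p, f)
  expect_equal(mean(p >= pol$lambda), f, tolerance = 1e-12)
})

test_that("the closed-form threshold map reproduces its worked values and limits", {
  expect_equal(closed_form_threshold(11.23, 0.5)$lambda, 0.1029,
               tolerance = 1e-3)
  expect_equal(round(closed_form_threshold(11.23, 0.5)$lambda, 1), 0.1)
  expect_equal(closed_form_threshold(1, 0.5)$lambda, 0.459,
               tolerance = 1e-3)
  expect_equal(closed_form_threshold(0, 0.5)$lambda, 0.55)
  # rho -> Inf limit is k/10
  expect_equal(closed_form_threshold(1e6, 0.5)$lambda, 0.05,
               tolerance = 1e-9)
  expect_error(closed_form_threshold(-1), class = "imbfall_value_error")
  expect_error(closed_form_threshold(2, k = 1), class = "imbfall_value_error")
})

test_that("the closed-form map decreases in rho and increases in k on a grid", {
  rhos <- seq(0, 40, length.out = 10)
  ks <- seq(0.1, 0.9, length.out = 10)
  for (k in ks) {
    lam <- vapply(rhos, function(r) closed_form_threshold(r, k)$lambda, 0)
    expect_true(all(diff(lam) < 0))
  }
  for (r in rhos) {
    lam <- vapply(ks, function(k) closed_form_threshold(r, k)$lambda, 0)
    expect_true(all(diff(lam) > 0))
  }
})

test_that("thresholding posteriors is order-preserving with an inclusive cutoff", {
  pol <- threshold_policy(0.1)
  expect_equal(apply_threshold(c(0.05, 0.15, 0.95), pol), c(0L, 1L, 1L))
  # exact equality classifies as fall
  expect_equal(apply_threshold(0.1, pol), 1L)
  # lambda = 0.5 reproduces argmax for binary softmax rows without ties
  set.seed(2)
  p_fall <- runif(100)
  p <- cbind(adl = 1 - p_fall, fall = p_fall)
  expect_equal(apply_threshold(p, threshold_policy(0.5)),
               as.integer(max.col(p) == 2))
  expect_error(threshold_policy(0), class = "imbfall_value_error")
  expect_error(threshold_policy(1), class = "imbfall_value_error")
})

test_that("class weights are inverse-frequency, averaging one over samples", {
  y <- c(rep(0L, 90), rep(1L, 10))
  w <- class_weights(y)
  expect_equal(unname(w), c(100 / 180, 100 / 20), tolerance = 1e-12)
  expect_equal(unname(round(w, 3)), c(0.556, 5))
  expect_equal(mean(w[y + 1L]), 1, tolerance = 1e-12)  # sample-mean 1
  expect_equal(unname(class_weights(c(0L, 1L, 0L, 1L))), c(1, 1))
  expect_error(class_weights(rep(0L, 5)), class = "imbfall_value_error")
})

test_that("weighted loss on balanced data equals the unweighted loss", {
  set.seed(8)
  p <- imbfall:::softmax(matrix(rnorm(40), 20))
  y <- rep(c(0L, 1L), 10)
  w <- class_weights(y)
  lw <- imbfall:::loss_ce(p, y, w[y + 1L])
  lu <- imbfall:::loss_ce(p, y)
  expect_equal(lw$loss, lu$loss, tolerance = 1e-12)
  expect_equal(lw$dlogits, lu$dlogits, tolerance = 1e-12)
})

test_that("focal loss reduces to weighted cross-entropy at gamma 0 and vanishes as p_t -> 1", {
  p <- c(0.3, 0.7, 0.9)
  y <- c(1L, 0L, 1L)
  expect_equal(focal_loss(p, y, gamma = 0, alpha = 0.5),
               0.5 * -log(ifelse(y == 1, p, 1 - p)), tolerance = 1e-12)
  # direct evaluation: p_t = 0.9, gamma = 2, alpha = 1 (minority sample)
  expect_equal(focal_loss(0.9, 1L, gamma = 2, alpha = 1),
               0.01 * -log(0.9), tolerance = 1e-10)
  expect_equal(round(focal_loss(0.9, 1L, gamma = 2, alpha = 1), 8),
               0.00105361)
  # limit: perfectly classified samples contribute nothing
  expect_lt(focal_loss(1 - 1e-12, 1L, gamma = 2, alpha = 0.5), 1e-20)
  expect_error(focal_loss(1, 1L), class = "imbfall_value_error")
  expect_error(focal_loss(0, 0L), class = "imbfall_value_error")
})

test_that("SMOTE interpolates on segments between minority neighbours, seeded", {
  set.seed(14)
  x <- array(rnorm(12 * 6 * 2), c(12, 6, 2))
  ws <- imbfall:::new_window_set(x, rep(1L, 12), sprintf("m%d", 1:12),
                                 rep(0L, 12), 10, 0.6)
  syn <- smote_windows(ws, n_new = 30, k_neighbors = 3, seed = 4)
  expect_equal(length(syn), 30)
  expect_true(all(syn$label == 1L))
  flat <- matrix(x, 12, 12)
  sflat <- matrix(syn$x, 30, 12)
  # componentwise betweenness: each synthetic point lies inside the
  # bounding box of SOME pair of real minority windows on every coordinate
  for (i in 1:30) {
    ok <- FALSE
    for (a in 1:12) for (b in 1:12) {
      lo <- pmin(flat[a, ], flat[b, ]); hi <- pmax(flat[a, ], flat[b, ])
      if (all(sflat[i, ] >= lo - 1e-9 & sflat[i, ] <= hi + 1e-9)) {
        # also exactly collinear: s = x_a + u (x_b - x_a) for scalar u
        d <- flat[b, ] - flat[a, ]
        u <- (sflat[i, ] - flat[a, ])[which.max(abs(d))] / d[which.max(abs(d))]
        if (max(abs(flat[a, ] + u * d - sflat[i, ])) < 1e-8) ok <- TRUE
      }
    }
    expect_true(ok)
  }
  # determinism and degenerate cases
  syn2 <- smote_windows(ws, n_new = 30, k_neighbors = 3, seed = 4)
  expect_identical(syn$x, syn2$x)
  expect_equal(length(smote_windows(ws, 0, 3, seed = 1)), 0)
  expect_error(smote_windows(ws, 5, k_neighbors = 12),
               class = "imbfall_value_error")
})

test_that("duplicated minority windows yield synthetic exact copies", {
  one <- matrix(rnorm(8), 4, 2)
  x <- array(0, c(2, 4, 2)); x[1, , ] <- one; x[2, , ] <- one
  syn <- smote_windows(x, n_new = 4, k_neighbors = 1, seed = 9)
  for (i in 1:4) expect_equal(syn$x[i, , ], one, tolerance = 1e-12)
})
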