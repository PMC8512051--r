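# Label convention throughout: 0 = ADL (positive class), 1 = fall
# (negative class); TP counts correctly classified ADL windows and TN
# correctly detected falls.

test_that("confusion counts follow the ADL-positive convention", {
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 1L, 1L, 0L)
  expect_equal(confusion(truth, pred),
               c(tp = 1, tn = 1, fp = 1, fn = 1))
  # perfect prediction
  expect_equal(confusion(truth, truth), c(tp = 2, tn = 2, fp = 0, fn = 0))
  expect_error(confusion(c(0, 1), c(0, 1, 1)), class = "imbfall_value_error")
})

test_that("confusion counts partition every evaluated window on random labels", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    truth <- rbinom(n, 1, runif(1))
    pred <- rbinom(n, 1, runif(1))
    cm <- confusion(truth, pred)
    expect_equal(sum(cm), n)
    # brute-force oracle over the four cells
    expect_equal(unname(cm["tp"]), sum(truth == 0 & pred == 0))
    expect_equal(unname(cm["tn"]), sum(truth == 1 & pred == 1))
    expect_equal(unname(cm["fp"]), sum(truth == 1 & pred == 0))
    expect_equal(unname(cm["fn"]), sum(truth == 0 & pred == 1))
  }
})

test_that("rates compute accuracy, sensitivity and specificity in percent", {
  # tn = fp = 0: specificity is undefined here (warned about); the
  # sensitivity arithmetic is what this case exercises
  r <- suppressWarnings(rates(c(tp = 197, tn = 0, fp = 0, fn = 3)))
  expect_equal(r$sensitivity, 98.5)
  r2 <- rates(c(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(r2), c(accuracy = 100, sensitivity = 100,
                             specificity = 100))
  r3 <- rates(c(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(unlist(r3), c(accuracy = 50, sensitivity = 50,
                             specificity = 50))
})

test_that("undefined rates are reported as missing with a warning, never 0 or 1", {
  expect_warning(r <- rates(c(tp = 3, tn = 0, fp = 0, fn = 1)),
                 "specificity undefined")
  expect_true(is.na(r$specificity))
  expect_false(is.na(r$sensitivity))
})

test_that("the F-beta score obeys its algebraic identities", {
  # equal arguments: score equals them, for any beta
  set.seed(31)
  for (i in 1:1000) {
    s <- runif(1, 0, 100)
    beta <- runif(1, 0.05, 5)
    expect_equal(f_score(s, s, beta), s, tolerance = 1e-9)
  }
  # zero specificity annihilates the score
  expect_equal(f_score(80, 0, 0.5), 0)
  expect_equal(f_score(0, 0, 0.5), 0)
  # bounded by its arguments
  for (i in 1:1000) {
    se <- runif(1, 0, 100); sp <- runif(1, 1e-6, 100)
    beta <- runif(1, 0.05, 5)
    f <- f_score(se, sp, beta)
    expect_gte(f, min(se, sp) - 1e-9)
    expect_lte(f, max(se, sp) + 1e-9)
  }
  # the working default beta = 0.5 weights specificity more
  expect_equal(f_score(99.33, 91.86, 0.5), 97.74, tolerance = 5e-3)
})

test_that("AUC enumerates rank pairs correctly on worked examples", {
  # positives {0.8, 0.4}, negatives {0.6, 0.2}: 3 of 4 pairs correct
  scores <- c(0.8, 0.4, 0.6, 0.2)
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(scores, labels), 0.75)
  # perfectly separated scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  # all scores equal: pure ties
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "imbfall_value_error")
})

test_that("rank and trapezoid AUC agree with each other and the pairwise oracle", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))     # both classes present
    # draw scores with deliberate ties on a coarse grid half the time
    scores <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.1), n, TRUE)
    a_rank <- roc_auc(scores, labels, method = "rank")
    a_trap <- roc_auc(scores, labels, method = "trapezoid")
    expect_equal(a_rank, a_trap, tolerance = 1e-9)
    expect_equal(a_rank, auc_pairs(scores, labels), tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(13)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.3)
  labels[1:2] <- c(0, 1)
  base <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(plogis(scores)), labels), base,
               tolerance = 1e-9)
  expect_equal(roc_auc(scores * 100 - 7, labels), base, tolerance = 1e-12)
})

test_that("ROC points run from (0,0) to (1,1) and support trapezoid integration", {
  set.seed(9)
  scores <- runif(30)
  labels <- c(rep(1, 15), rep(0, 15))
  pts <- roc_points(scores, labels)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
})

test_that("eval_report assembles counts, rates, F-beta and AUC coherently", {
  set.seed(4)
  truth <- c(rep(0L, 80), rep(1L, 20))
  scores <- ifelse(truth == 1, runif(100, 0.3, 1), runif(100, 0, 0.7))
  pred <- as.integer(scores >= 0.5)
  rep_ <- eval_report(truth, pred, scores = scores, beta = 0.5)
  expect_s3_class(rep_, "eval_report")
  expect_equal(rep_$n, 100)
  expect_equal(sum(rep_$counts), 100)
  expect_equal(rep_$f_score,
               f_score(rep_$sensitivity, rep_$specificity, 0.5))
  expect_equal(rep_$auc, 100 * roc_auc(scores, truth), tolerance = 1e-12)
  expect_output(print(rep_), "positive = ADL")
  df <- as.data.frame(rep_)
  expect_equal(df$tp + df$tn + df$fp + df$fn, 100)
})
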