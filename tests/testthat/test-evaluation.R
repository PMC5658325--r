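test_that("roc_curve has valid endpoints and monotone sweep", {
  set.seed(4)
  coh <- binormal_cohort(15, 20, 0.8)
  curve <- roc_curve(coh$scores, coh$labels)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  # perfect separation passes through (0, 1)
  sep <- roc_curve(c(3, 2, 1), c(TRUE, TRUE, FALSE))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  # all-tied scores give the diagonal
  flat <- roc_curve(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(flat$fpr, flat$tpr)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), class = "lfa_roc_error")
})

test_that("DeLong AUC equals the exhaustive pair-counting oracle", {
  set.seed(100)
  for (i in 1:50) {
    n_pos <- sample(2:25, 1)
    n_neg <- sample(2:25, 1)
    scores <- round(rnorm(n_pos + n_neg), sample(0:2, 1))  # force ties
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    expect_equal(auc_delong(scores, labels)$auc,
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("DeLong AUC and variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(12)
  coh <- binormal_cohort(30, 40, 0.836)
  ours <- auc_delong(coh$scores, coh$labels)
  theirs <- pROC::roc(response = coh$labels, predictor = coh$scores,
                      levels = c(FALSE, TRUE), direction = "<",
                      quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
  expect_equal(ours$variance, as.numeric(pROC::var(theirs)),
               tolerance = 1e-10)
})

test_that("AUC analytic limits and symmetries hold", {
  expect_equal(auc_delong(c(3, 2, 1), c(TRUE, TRUE, FALSE))$auc, 1)
  expect_equal(auc_delong(c(1, 2, 1, 2),
                          c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  set.seed(9)
  coh <- binormal_cohort(12, 18, 0.75)
  a <- auc_delong(coh$scores, coh$labels)$auc
  # label swap antisymmetry
  expect_equal(auc_delong(coh$scores, !coh$labels)$auc, 1 - a)
  # invariance under strictly monotone score transforms
  expect_equal(auc_delong(exp(coh$scores), coh$labels)$auc, a)
  expect_equal(auc_delong(rank(coh$scores), coh$labels)$auc, a)
  # trapezoidal area under the empirical curve equals the statistic
  curve <- roc_curve(coh$scores, coh$labels)
  trap <- sum(diff(curve$fpr) * (head(curve$tpr, -1) +
                                   tail(curve$tpr, -1)) / 2)
  expect_equal(trap, a, tolerance = 1e-12)
})

test_that("bootstrap AUC is seeded, degenerate-exact, and tracks truth", {
  boot1 <- auc_bootstrap(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE),
                         iterations = 200, seed = 6)
  expect_equal(boot1$auc, 1)
  expect_equal(diff(boot1$ci_95), 0)
  boot2 <- auc_bootstrap(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE),
                         iterations = 200, seed = 6)
  expect_identical(boot1, boot2)
  set.seed(77)
  coh <- binormal_cohort(100, 100, 0.836)
  boot <- auc_bootstrap(coh$scores, coh$labels, iterations = 500, seed = 1)
  expect_equal(boot$auc, boot$auc_observed, tolerance = 0.02)
})

test_that("diagnostic accuracy reports exact rationals", {
  acc <- diagnostic_accuracy(rep("below", 21),
                             c(rep("below", 19), rep("at_or_above", 2)))
  expect_equal(acc$exact, "19/21")
  expect_equal(round(acc$percent, 1), 90.5)
  expect_equal(diagnostic_accuracy(1:5, 1:5)$accuracy, 1)
  expect_error(diagnostic_accuracy(1:3, 1:2), class = "lfa_input_error")
  expect_error(diagnostic_accuracy(character(0), character(0)),
               class = "lfa_input_error")
})

test_that("rmse matches hand arithmetic and Monte-Carlo truth", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(10, 10), c(13, 7)), 3)
  ref <- withr::with_seed(15, runif(5000, 20, 120))
  pred <- withr::with_seed(16, ref + rnorm(5000, 0, 5.4))
  err <- rmse(ref, pred)
  expect_gt(err, 5.1)
  expect_lt(err, 5.7)
})

test_that("evaluate_cohort assembles the full report", {
  set.seed(30)
  ref <- runif(60, 10, 100)
  pred <- pmax(0, ref + rnorm(60, 0, 6))
  rep60 <- evaluate_cohort(ref, pred, cutoff = 50, iterations = 200,
                           seed = 2)
  expect_equal(rep60$n, 60)
  expect_s3_class(rep60$delong, "roc_result")
  expect_s3_class(rep60$bootstrap, "roc_result")
  expect_true(rep60$delong$auc > 0.8)    # concordant predictions
  expect_equal(rep60$rmse_nmol_L, rmse(ref, pred))
})
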