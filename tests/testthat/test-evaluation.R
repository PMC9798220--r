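test_that("edge vectorization follows the row-major upper triangle", {
  expect_equal(nrow(edge_index(116)), 6670)
  expect_equal(edge_index(4),
               cbind(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4)))
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 12; W[1, 3] <- W[3, 1] <- 13
  W[1, 4] <- W[4, 1] <- 14; W[2, 3] <- W[3, 2] <- 23
  W[2, 4] <- W[4, 2] <- 24; W[3, 4] <- W[4, 3] <- 34
  expect_equal(edge_vector(W), c(12, 13, 14, 23, 24, 34))
  expect_equal(edge_vector(matrix(0, 5, 5)), rep(0, 10))
  A <- matrix(0, 4, 4); A[1, 2] <- 1e-6
  expect_error(edge_vector(A), "asymmetric")
})

test_that("t-test selection is calibrated and powered", {
  set.seed(20)
  n <- 30
  X <- matrix(stats::rnorm(2 * n * 400), 2 * n, 400)
  y <- rep(c(0, 1), each = n)
  X[y == 1, 1:10] <- X[y == 1, 1:10] + 2     # two pooled-sd shift
  sel <- ttest_select(X, y)
  expect_true(all(sel$mask[1:10]))
  frac_null <- mean(sel$mask[-(1:10)])
  expect_lt(abs(frac_null - 0.05), 2.58 * sqrt(0.05 * 0.95 / 390) + 1e-9)
  # oracle cross-check of the pooled t statistic on one edge
  tt <- stats::t.test(X[y == 1, 1], X[y == 0, 1], var.equal = TRUE)
  expect_equal(sel$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(sel$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("degenerate edges and single-class inputs are rejected", {
  X <- matrix(stats::rnorm(40), 20, 2)
  X[, 2] <- 5
  y <- rep(c(0, 1), 10)
  expect_warning(sel <- ttest_select(X, y), "zero variance")
  expect_false(sel$mask[2])
  expect_error(ttest_select(X, rep(1, 20)), "both classes")
})

test_that("confusion metrics follow their closed forms", {
  expect_equal(confusion_metrics(1, 1, 0, 0),
               c(acc = 100, sen = 100, spe = 100))
  m <- confusion_metrics(3, 4, 2, 1)
  expect_equal(unname(m["acc"]), 70)
  expect_equal(unname(m["sen"]), 75)
  expect_equal(unname(m["spe"]), 66.67, tolerance = 0.005)
  expect_equal(confusion_metrics(0, 5, 0, 5),
               c(acc = 50, sen = 0, spe = 100))
  # 1000 random tables against a direct-count oracle
  set.seed(21)
  for (i in 1:1000) {
    cts <- stats::rmultinom(1, 40, rep(0.25, 4))
    tp <- cts[1]; tn <- cts[2]; fp <- cts[3]; fn <- cts[4]
    if (tp + fn == 0 || tn + fp == 0) next
    m <- confusion_metrics(tp, tn, fp, fn)
    expect_equal(unname(m["acc"]), (tp + tn) / 40 * 100)
    lo <- min(m["sen"], m["spe"]); hi <- max(m["sen"], m["spe"])
    expect_true(m["acc"] >= lo - 1e-9 && m["acc"] <= hi + 1e-9)
  }
})

test_that("linearly separable features classify perfectly", {
  set.seed(22)
  n <- 40
  y <- rep(c("control", "patient"), each = n / 2)
  X <- matrix(stats::rnorm(n * 50), n)
  X[y == "patient", 1] <- X[y == "patient", 1] + 10
  cvr <- nested_cv_classify(X, y, n_repeats = 3, seed = 5)
  expect_equal(unname(cvr$per_repeat[, "acc"]), c(100, 100, 100))
  expect_equal(cvr$auc_mean, 100)
})

test_that("hyperparameter choice and selection never see test folds", {
  set.seed(23)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * 30), n)
  X[y == 1, 1:3] <- X[y == 1, 1:3] + 1.5
  feats <- list("1" = X, "2" = X + stats::rnorm(n * 30, sd = 0.01))
  cvr <- nested_cv_classify(feats, y, grid = c(1, 2), n_repeats = 2,
                            seed = 9)
  # reconstruct fold 1 of repeat 1 externally and re-derive the choice
  folds <- mbnf:::stratified_folds(y, 5, seed = mbnf:::derive_seed(9, 1))
  tr <- folds != 1
  inner <- mbnf:::stratified_folds(y[tr], 5,
                                   seed = mbnf:::derive_seed(9, 1, 1))
  accs <- vapply(1:2, function(gi)
    mbnf:::inner_cv_accuracy(feats[[gi]][tr, ], y[tr], inner, 0.05, 1),
    numeric(1))
  expect_equal(cvr$chosen[1, 1], c(1, 2)[which.max(accs)])
  # flipping only test-fold labels cannot change the trained decision rule:
  # selection + fit on the same training rows yields identical predictions
  sel <- ttest_select(feats[[which.max(accs)]][tr, ], y[tr])
  keep <- mbnf:::selected_columns(sel)
  fit1 <- mbnf:::fit_svm(feats[[which.max(accs)]][tr, keep], y[tr],
                         feats[[which.max(accs)]][!tr, keep])
  sel2 <- ttest_select(feats[[which.max(accs)]][tr, ], y[tr])
  expect_identical(sel$mask, sel2$mask)
  expect_identical(fit1$pred, mbnf:::fit_svm(
    feats[[which.max(accs)]][tr, keep], y[tr],
    feats[[which.max(accs)]][!tr, keep])$pred)
})

test_that("paired method comparison behaves at the edge cases", {
  a <- c(80, 82, 81, 79, 83)
  res <- paired_ttest_compare(a, a)
  expect_true(is.na(res$p_value))
  expect_false(res$significant)
  set.seed(24)
  b <- a + 5 + stats::rnorm(5, sd = 0.01)
  res2 <- paired_ttest_compare(b, a)
  expect_lt(res2$p_value, 0.05)
  expect_true(res2$significant)
  expect_gt(res2$mean_diff, 4.9)
  expect_error(paired_ttest_compare(1, 1), "length")
})

test_that("network noise leaves matrices symmetric and sd = 0 is a no-op", {
  set.seed(25)
  nets <- lapply(1:24, function(i) {
    W <- random_symmetric(8, 300 + i)
    if (i <= 12) W[1, 2] <- W[2, 1] <- W[1, 2] + 1.2
    W
  })
  y <- rep(c("patient", "control"), each = 12)
  tab <- noise_robustness_experiment(nets, y, sd_grid = c(0, 0.3),
                                     n_repeats = 2, seed = 6)
  base <- nested_cv_classify(edge_feature_matrix(nets), y,
                             n_repeats = 2, seed = 6)
  expect_equal(tab$acc_mean[1], base$acc_mean)
  expect_error(noise_robustness_experiment(nets, y, c(0.3, 0.1),
                                           n_repeats = 2, seed = 6),
               "non-decreasing")
  expect_error(noise_robustness_experiment(nets, y, c(-0.1, 0.1),
                                           n_repeats = 2, seed = 6),
               ">= 0")
})
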