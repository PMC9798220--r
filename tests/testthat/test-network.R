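test_that("normalization standardizes every row", {
  expect_equal(as.vector(normalize_roi_signals(matrix(c(1, 2, 3), 1))),
               c(-1, 0, 1))
  set.seed(1)
  X <- matrix(stats::rnorm(100), 5, 20)
  N <- normalize_roi_signals(X)
  man <- t(apply(X, 1, function(r) (r - mean(r)) / stats::sd(r)))
  expect_lt(max(abs(N - man)), 1e-12)
  X[2, ] <- 7
  expect_error(normalize_roi_signals(X), "ROI\\(s\\) 2")
})

test_that("pearson networks equal the scalar-loop oracle", {
  set.seed(2)
  X <- matrix(stats::rnorm(40), 4, 10)
  W <- pearson_network(X)
  expect_lt(max(abs(unclass(W) - oracle_pearson(X))), 1e-12)
  # perfect and perfectly inverted pairs
  X2 <- rbind(X[1, ], X[1, ], -X[1, ])
  W2 <- pearson_network(X2)
  expect_equal(W2[1, 2], 1)
  expect_equal(W2[1, 3], -1)
  expect_error(pearson_network(rbind(X[1, ], rep(2, 10))), "constant")
})

test_that("thresholding keeps the strongest edges with ties retained", {
  set.seed(3)
  A <- random_symmetric(6, 3)
  expect_equal(unclass(threshold_network(A, 1.0)), A, ignore_attr = TRUE)
  half <- threshold_network(A, 0.5)
  expect_lt(max(abs(unclass(half) - oracle_threshold(A, 0.5))), 1e-15)
  # unique maximum edge survives a just-below-1/E fraction
  E <- 15
  top1 <- threshold_network(A, 0.9 / E)
  expect_equal(sum(unclass(top1)[upper.tri(A)] != 0), 1)
  expect_equal(max(abs(unclass(top1))), max(abs(A)))
  # ties at the cutoff are all kept
  B <- matrix(0, 4, 4); B[1, 2] <- B[2, 1] <- 0.9
  B[1, 3] <- B[3, 1] <- 0.5; B[2, 4] <- B[4, 2] <- 0.5
  kept <- threshold_network(B, 2 / 6)   # cutoff lands on the tied 0.5s
  expect_equal(sum(unclass(kept)[upper.tri(B)] != 0), 3)
  expect_error(threshold_network(A, 0), "keep_fraction")
  expect_error(threshold_network(A, 1.2), "keep_fraction")
})

test_that("retained edge count tracks keep_fraction", {
  set.seed(4)
  A <- random_symmetric(10, 5)
  for (kf in c(0.2, 0.5, 0.8)) {
    W <- threshold_network(A, kf)
    kept <- sum(unclass(W)[upper.tri(W)] != 0)
    expect_equal(kept, ceiling(kf * 45))  # no ties in continuous data
  }
})

test_that("a large enough lambda yields the empty sparse network", {
  set.seed(5)
  X <- normalize_roi_signals(matrix(stats::rnorm(80), 4, 20))
  G <- X %*% t(X)
  lam <- 2 * max(abs(G[upper.tri(G)])) + 1e-6
  W <- sparse_representation_network(X, lambda = lam)
  expect_true(all(W == 0))
})

test_that("sparse representation recovers a planted dependency", {
  set.seed(6)
  x2 <- stats::rnorm(50)
  X <- rbind(0.9 * x2 + 0.1 * stats::rnorm(50), x2,
             stats::rnorm(50), stats::rnorm(50), stats::rnorm(50))
  W <- sparse_representation_network(X, lambda = 1)
  expect_equal(which.max(abs(W[1, -1])), 1)  # strongest partner is ROI 2
})

test_that("sparse representation solutions satisfy the lasso KKT conditions", {
  set.seed(7)
  X <- normalize_roi_signals(matrix(stats::rnorm(6 * 40), 6, 40))
  lambda <- 0.5
  # re-solve row-wise (pre-symmetrization) and check stationarity
  for (i in 1:6) {
    idx <- setdiff(1:6, i)
    A <- t(X[idx, , drop = FALSE])
    fit <- mbnf:::lasso_cd(crossprod(A), drop(crossprod(A, X[i, ])), lambda)
    r <- X[i, ] - A %*% fit$w
    g <- drop(crossprod(A, r))
    expect_true(all(abs(g[fit$w == 0]) <= lambda / 2 + 1e-5))
    nz <- fit$w != 0
    expect_true(all(abs(g[nz] - lambda / 2 * sign(fit$w[nz])) <= 1e-5))
  }
})

test_that("coordinate descent matches the glmnet oracle objective", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  for (P in c(4, 7, 10)) {
    X <- normalize_roi_signals(matrix(stats::rnorm(P * 30), P, 30))
    lambda <- 0.4
    for (i in seq_len(P)) {
      idx <- setdiff(seq_len(P), i)
      A <- t(X[idx, , drop = FALSE])
      y <- X[i, ]
      mine <- mbnf:::lasso_cd(crossprod(A), drop(crossprod(A, y)), lambda)
      gfit <- glmnet::glmnet(A, y, lambda = lambda / (2 * length(y)),
                             intercept = FALSE, standardize = FALSE,
                             thresh = 1e-14)
      w_g <- as.numeric(gfit$beta)
      expect_lt(abs(sr_objective(y, A, mine$w, lambda) -
                    sr_objective(y, A, w_g, lambda)), 1e-6)
    }
  }
})

test_that("the objective is monotone over sweeps and sparsity over lambda", {
  set.seed(9)
  X <- normalize_roi_signals(matrix(stats::rnorm(8 * 30), 8, 30))
  A <- t(X[-1, ])
  y <- X[1, ]
  G <- crossprod(A); b <- drop(crossprod(A, y))
  # one sweep at a time: objective never increases
  obj <- function(w) sr_objective(y, A, w, 0.3)
  w_prev <- numeric(7); o_prev <- obj(w_prev)
  w_run <- w_prev
  for (s in 1:15) {
    w_run <- mbnf:::lasso_cd(G, b, 0.3, tol = 0, max_sweeps = s)$w
    o_run <- obj(w_run)
    expect_lte(o_run, o_prev + 1e-12)
    o_prev <- o_run
  }
  # support shrinks along the lambda grid
  nnz <- vapply(seq(0.1, 1, by = 0.05), function(l)
    sum(sparse_representation_network(X, l) != 0), numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("connectivity matrices enforce their structural invariants", {
  A <- random_symmetric(5, 10)
  Askew <- A; Askew[1, 2] <- Askew[1, 2] + 1e-6
  expect_error(connectivity_matrix(Askew, kind = "sr"), "asymmetric")
  expect_error(connectivity_matrix(A + diag(5) * 0.5, kind = "sr"),
               "diagonal")
  B <- A; diag(B) <- 1; B[1, 2] <- B[2, 1] <- 1.5
  expect_error(connectivity_matrix(B, kind = "pc"), "1, 1")
})
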