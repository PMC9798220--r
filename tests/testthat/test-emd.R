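test_that("a monotone ramp yields no IMFs and is returned as residual", {
  x <- seq(0, 5, length.out = 64)
  z <- emd(x)
  expect_length(z$imfs, 0)
  expect_equal(z$residual, x)
})

test_that("sifting reconstructs the input exactly", {
  set.seed(42)
  for (i in 1:10) {
    x <- stats::rnorm(137)
    z <- emd(x)
    recon <- Reduce(`+`, z$imfs, numeric(137)) + z$residual
    expect_lt(max(abs(x - recon)), 1e-9)
  }
})

test_that("a single tone on a slow trend separates into IMF1 at the tone", {
  t <- seq_len(512)
  x <- sin(2 * pi * 0.1 * t) + 0.05 * t
  z <- emd(x)
  expect_gte(length(z$imfs), 1)
  f1 <- average_frequency(z$imfs[[1]], TR = 1)
  expect_lt(abs(f1 - 0.1) / 0.1, 0.1)
  # independent spectral-centroid oracle agrees
  expect_lt(abs(oracle_centroid(z$imfs[[1]], 1) - f1), 1e-8)
})

test_that("emd rejects degenerate inputs", {
  expect_error(emd(rep(1, 50)), "constant")
  expect_error(emd(c(1, 2, 3)), "length")
  expect_error(emd(c(stats::rnorm(49), NA)), "finite")
})

test_that("eemd with zero noise and a single trial reproduces plain emd", {
  set.seed(3)
  x <- stats::rnorm(137)
  a <- emd(x)
  b <- eemd(x, eemd_params(ensemble_size = 1L, noise_amplitude = 0))
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residual, b$residual)
})

test_that("eemd is bit-reproducible under a fixed seed", {
  set.seed(8)
  x <- stats::rnorm(137)
  p <- eemd_params(ensemble_size = 10L, seed = 123L)
  a <- eemd(x, p)
  b <- eemd(x, p)
  expect_identical(a, b)
  expect_lt(max(abs(x - Reduce(`+`, a$imfs) - a$residual)), 1e-9)
})

test_that("eemd separates a two-tone signal into the right bands", {
  t_sec <- (seq_len(500) - 1) * 3
  x <- sin(2 * pi * 0.12 * t_sec) + sin(2 * pi * 0.02 * t_sec)
  z <- eemd(x, eemd_params(ensemble_size = 50L, noise_amplitude = 0.2,
                           seed = 11L))
  f1 <- average_frequency(z$imfs[[1]], TR = 3)
  expect_lt(abs(f1 - 0.12) / 0.12, 0.25)
  low_sum <- Reduce(`+`, z$imfs[-1])
  pg <- oracle_periodogram(low_sum, 3)
  expect_lt(abs(pg$f[which.max(pg$power)] - 0.02), 2 / (500 * 3))
})

test_that("larger ensembles stabilize the averaged IMF1", {
  set.seed(5)
  x <- stats::rnorm(200)
  half_diff <- function(M) {
    a <- eemd(x, eemd_params(ensemble_size = M, seed = 21L))
    b <- eemd(x, eemd_params(ensemble_size = M, seed = 22L))
    sqrt(mean((a$imfs[[1]] - b$imfs[[1]])^2))
  }
  expect_lt(half_diff(40L), half_diff(20L))
})

test_that("average_frequency matches known spectra", {
  t <- seq_len(512)
  tone <- sin(2 * pi * 0.1 * t)
  expect_lt(abs(average_frequency(tone, 1) - 0.1), 1 / 512)
  set.seed(17)
  wn <- stats::rnorm(2048)
  expect_lt(abs(average_frequency(wn, 1) - 0.25) / 0.25, 0.1)
  expect_error(average_frequency(numeric(64), 1), "zero")
})

test_that("zero-crossing frequency estimator agrees on a pure tone", {
  t <- seq_len(1000)
  tone <- sin(2 * pi * 0.05 * t)
  expect_lt(abs(average_frequency(tone, 1, method = "zero_crossing") - 0.05),
            0.002)
})

test_that("split_bands assigns IMF1 to high and the rest to low", {
  t <- seq_len(137)
  mk <- function(...) {
    imfs <- list(...)
    structure(list(imfs = imfs, residual = numeric(137) + 0.5,
                   source_length = 137L), class = "imf_set")
  }
  i1 <- sin(2 * pi * 0.3 * t); i2 <- sin(2 * pi * 0.1 * t)
  i3 <- sin(2 * pi * 0.02 * t)
  b <- split_bands(list(mk(i1, i2, i3), mk(i1, i2, i3)))
  expect_equal(b$high[1, ], i1)
  expect_equal(b$low[2, ], i2 + i3)
  expect_warning(b1 <- split_bands(list(mk(i1))), "single IMF")
  expect_true(all(b1$low == 0))
  expect_error(split_bands(list()), "at least one")
  # residual folded in on request
  b2 <- split_bands(list(mk(i1, i2)), include_residual = TRUE)
  expect_equal(b2$low[1, ], i2 + 0.5 * rep(1, 137))
})

test_that("high band rows are faster than low band rows on cohort signals", {
  co <- study_cohort()
  X <- normalize_roi_signals(co$subjects[[1]]$values)
  bands <- decompose_signals(X, method = "eemd",
                             params = eemd_params(ensemble_size = 20L,
                                                  seed = 4L))
  fh <- apply(bands$high, 1, average_frequency, TR = 3)
  fl <- apply(bands$low, 1, average_frequency, TR = 3)
  expect_gte(mean(fh > fl), 0.95)
})
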