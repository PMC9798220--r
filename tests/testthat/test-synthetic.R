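test_that("band-limited latents concentrate their spectrum in band", {
  x <- generate_band_limited_latent(137, 3, c(0.06, 0.15), seed = 1)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(x), 1, tolerance = 1e-12)
  expect_gte(oracle_band_mass(x, 3, c(0.06, 0.15)), 0.9)
})

test_that("latents respect the Nyquist bound and the seed", {
  expect_error(generate_band_limited_latent(137, 3, c(0.2, 0.3)),
               "Nyquist")
  a <- generate_band_limited_latent(137, 3, c(0.015, 0.06), seed = 5)
  b <- generate_band_limited_latent(137, 3, c(0.015, 0.06), seed = 5)
  expect_identical(a, b)
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(low_band = c(0.07, 0.1),
                           high_band = c(0.06, 0.15)), "low_band")
  expect_error(cohort_spec(low_band = c(0.1, 0.2)), "within")
  expect_error(cohort_spec(effect_size = 0.5, within_corr = 0.6),
               "unattainable")
  expect_error(cohort_spec(effect_edges = cbind(3, 2)), "i < j")
  expect_error(cohort_spec(communities_low = rep(1, 5)), "cover")
  # a path (1-2, 2-3 without 1-3) is not a clique
  expect_error(cohort_spec(effect_edges = rbind(c(1, 2), c(2, 3))),
               "clique")
  # a complete triangle is
  expect_s3_class(cohort_spec(effect_edges = rbind(c(1, 2), c(2, 3),
                                                   c(1, 3))),
                  "cohort_spec")
})

test_that("a null effect yields identical truth matrices across groups", {
  spec <- cohort_spec(effect_size = 0, seed = 2)
  co <- generate_cohort(spec)
  expect_identical(co$truth$high$control, co$truth$high$patient)
  expect_identical(co$truth$low$control, co$truth$low$patient)
})

test_that("cohort generation is bit-reproducible and well-formed", {
  spec <- cohort_spec(n_per_group = 4, P = 8, seed = 31)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a$subjects, 8)
  for (s in a$subjects) {
    expect_identical(dim(s$values), c(8L, 137L))
    expect_true(all(is.finite(s$values)))
  }
  expect_setequal(unique(cohort_labels(a)), c("control", "patient"))
})

test_that("planted high-band effects shift empirical correlations", {
  spec <- cohort_spec(effect_band = "high", seed = 7)  # P=20, n=30, es=0.4
  co <- generate_cohort(spec)
  y <- cohort_labels(co) == "patient"
  mean_eff_pc <- function(idx) {
    acc <- 0
    for (i in idx) {
      Xf <- filter_band(co$subjects[[i]]$values, spec$high_band, spec$TR)
      W <- stats::cor(t(Xf))
      acc <- acc + mean(W[spec$effect_edges])
    }
    acc / length(idx)
  }
  shift <- mean_eff_pc(which(y)) - mean_eff_pc(which(!y))
  expect_gt(shift, 0.2)
})

test_that("a single shared latent gives perfect within-community correlation", {
  spec <- cohort_spec(n_per_group = 2, P = 6, noise_sd = 0,
                      within_corr = 1, effect_size = 0,
                      communities_low = rep(1, 6),
                      communities_high = rep(1, 6), seed = 3)
  co <- generate_cohort(spec)
  Xf <- filter_band(co$subjects[[1]]$values, spec$low_band, spec$TR)
  W <- stats::cor(t(Xf))
  expect_true(all(abs(W - 1) < 1e-6))
})

test_that("averaged ROI periodograms peak inside both configured bands", {
  spec <- cohort_spec(n_per_group = 2, noise_sd = 0.3, seed = 13)
  co <- generate_cohort(spec)
  X <- co$subjects[[1]]$values
  pg <- oracle_periodogram(X[1, ], spec$TR)
  avg <- rowMeans(vapply(seq_len(nrow(X)), function(i)
    oracle_periodogram(X[i, ], spec$TR)$power, numeric(nrow(pg))))
  in_low <- pg$f >= spec$low_band[1] & pg$f <= spec$low_band[2]
  in_high <- pg$f > spec$high_band[1] & pg$f <= spec$high_band[2]
  outside <- !in_low & !in_high
  expect_gt(max(avg[in_low]), max(avg[outside]))
  expect_gt(max(avg[in_high]), max(avg[outside]))
})

test_that("band-filtered correlations converge to the truth as T grows", {
  errs <- vapply(c(137L, 500L, 2000L), function(T_len) {
    spec <- cohort_spec(n_per_group = 2, P = 10, T_len = T_len,
                        noise_sd = 0, seed = 41)
    co <- generate_cohort(spec)
    Xf <- filter_band(co$subjects[[1]]$values, spec$high_band, spec$TR)
    sqrt(sum((stats::cor(t(Xf)) - co$truth$high$control)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
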