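# Independent oracles: deliberately naive implementations (scalar loops,
# direct DFT) kept free of the package's computational paths.

# Pearson correlation matrix via explicit scalar loops.
oracle_pearson <- function(X) {
  P <- nrow(X); n <- ncol(X)
  W <- matrix(0, P, P)
  for (i in seq_len(P)) {
    for (j in seq_len(P)) {
      xi <- X[i, ] - sum(X[i, ]) / n
      xj <- X[j, ] - sum(X[j, ]) / n
      num <- 0; di <- 0; dj <- 0
      for (t in seq_len(n)) {
        num <- num + xi[t] * xj[t]
        di <- di + xi[t]^2
        dj <- dj + xj[t]^2
      }
      W[i, j] <- num / sqrt(di * dj)
    }
  }
  W
}

# One-sided periodogram by direct DFT summation (no fft()).
oracle_periodogram <- function(x, TR) {
  n <- length(x)
  x <- x - mean(x)
  ks <- seq_len(floor(n / 2))
  p <- vapply(ks, function(k) {
    ang <- 2 * pi * k * (seq_len(n) - 1) / n
    sum(x * cos(ang))^2 + sum(x * sin(ang))^2
  }, numeric(1))
  data.frame(f = ks / (n * TR), power = p)
}

oracle_centroid <- function(x, TR) {
  pg <- oracle_periodogram(x, TR)
  sum(pg$f * pg$power) / sum(pg$power)
}

# Fraction of spectral mass inside [band[1], band[2]].
oracle_band_mass <- function(x, TR, band) {
  pg <- oracle_periodogram(x, TR)
  sum(pg$power[pg$f >= band[1] & pg$f <= band[2]]) / sum(pg$power)
}

# Magnitude thresholding by explicit sort-and-cut.
oracle_threshold <- function(W, keep_fraction) {
  P <- nrow(W)
  out <- W
  mags <- c()
  for (i in seq_len(P - 1)) for (j in (i + 1):P) mags <- c(mags, abs(W[i, j]))
  cutoff <- sort(mags, decreasing = TRUE)[ceiling(keep_fraction * length(mags))]
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    if (abs(W[i, j]) < cutoff) out[i, j] <- out[j, i] <- 0
  }
  out
}

# FV by per-ROI loops over profile pairs.
oracle_fv <- function(w_high, w_low) {
  P <- nrow(w_high)
  out <- numeric(P)
  for (i in seq_len(P)) {
    a <- w_high[-i, i]; b <- w_low[-i, i]
    am <- mean(a); bm <- mean(b)
    out[i] <- 1 - sum((a - am) * (b - bm)) /
      sqrt(sum((a - am)^2) * sum((b - bm)^2))
  }
  out
}

# Random symmetric zero-diagonal matrix.
random_symmetric <- function(P, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(P * P), P)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# Eq. 3 objective for one node's weights.
sr_objective <- function(y, A, w, lambda) {
  sum((y - A %*% w)^2) + lambda * sum(abs(w))
}
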