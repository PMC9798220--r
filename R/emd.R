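# Empirical mode decomposition (EMD), its ensemble variant (EEMD), IMF
# frequency summaries and the high/low band split used throughout the
# framework.
#
# Sifting follows the classical scheme: cubic-spline upper/lower envelopes
# through local maxima/minima (mirror-extended at the ends), iterated until
# the Cauchy SD criterion falls below a threshold; decomposition stops once
# the residual is monotone (fewer than 2 interior extrema).

# Indices of interior local maxima / minima. Plateaus are handled by
# carrying the previous non-zero slope sign, which places a single
# extremum at the downstream edge of a flat run.
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) == 0L) return(list(maxima = integer(0), minima = integer(0)))
  # fill zero slopes with the previous non-zero sign (leading zeros get the
  # first non-zero sign so no spurious extremum appears at the boundary)
  if (nz[1L] > 1L) s[seq_len(nz[1L] - 1L)] <- s[nz[1L]]
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  ch <- diff(s)
  list(maxima = which(ch < 0) + 1L, minima = which(ch > 0) + 1L)
}

# Mirror extrema beyond one end of the record (symmetrized boundary
# conditions in the style of Rilling's reference EMD). The reflection axis
# is the outermost extremum unless the end sample overshoots the envelope
# on that side, in which case the end sample itself becomes a knot and the
# axis. `n_ext` extrema are reflected.
extend_end <- function(x, maxima, minima, side = c("left", "right"),
                       n_ext = 2L) {
  side <- match.arg(side)
  n <- length(x)
  if (side == "right") {       # reuse the left-end logic on the flipped series
    e <- extend_end(rev(x), n + 1L - rev(maxima), n + 1L - rev(minima),
                    "left", n_ext)
    return(list(max_pos = rev(n + 1L - e$max_pos), max_val = rev(e$max_val),
                min_pos = rev(n + 1L - e$min_pos), min_val = rev(e$min_val)))
  }
  first_is_max <- maxima[1L] < minima[1L]
  if (first_is_max) {
    if (x[1L] > x[minima[1L]]) {            # start sits above the first min
      sym <- maxima[1L]
      mx <- maxima[seq_len(min(length(maxima) - 1L, n_ext)) + 1L]
      mn <- minima[seq_len(min(length(minima), n_ext))]
    } else {                                # start undershoots: clamp to it
      sym <- 1L
      mx <- maxima[seq_len(min(length(maxima), n_ext))]
      mn <- c(1L, minima[seq_len(min(length(minima), n_ext - 1L))])
    }
  } else {
    if (x[1L] < x[maxima[1L]]) {
      sym <- minima[1L]
      mn <- minima[seq_len(min(length(minima) - 1L, n_ext)) + 1L]
      mx <- maxima[seq_len(min(length(maxima), n_ext))]
    } else {
      sym <- 1L
      mn <- minima[seq_len(min(length(minima), n_ext))]
      mx <- c(1L, maxima[seq_len(min(length(maxima), n_ext - 1L))])
    }
  }
  # if the reflection fails to reach beyond the record start, fall back to
  # reflecting about the first sample
  if (length(mx) == 0L || length(mn) == 0L ||
      min(2L * sym - mx, 2L * sym - mn) >= 1L) {
    sym <- 1L
    mx <- maxima[seq_len(min(length(maxima), n_ext))]
    mn <- minima[seq_len(min(length(minima), n_ext))]
  }
  list(max_pos = 2L * sym - rev(mx), max_val = x[rev(mx)],
       min_pos = 2L * sym - rev(mn), min_val = x[rev(mn)])
}

# Upper/lower cubic-spline envelopes with symmetrized boundary extension.
envelopes <- function(x, maxima, minima, n_ext = 2L) {
  n <- length(x)
  le <- extend_end(x, maxima, minima, "left", n_ext)
  re <- extend_end(x, maxima, minima, "right", n_ext)
  up_pos <- c(le$max_pos, maxima, re$max_pos)
  up_val <- c(le$max_val, x[maxima], re$max_val)
  lo_pos <- c(le$min_pos, minima, re$min_pos)
  lo_val <- c(le$min_val, x[minima], re$min_val)
  ku <- !duplicated(up_pos)
  kl <- !duplicated(lo_pos)
  list(upper = stats::spline(up_pos[ku], up_val[ku], xout = seq_len(n),
                             method = "fmm")$y,
       lower = stats::spline(lo_pos[kl], lo_val[kl], xout = seq_len(n),
                             method = "fmm")$y)
}

sift_imf <- function(r, max_sift, sd_threshold) {
  h <- r
  for (it in seq_len(max_sift)) {
    ext <- find_extrema(h)
    if (length(ext$maxima) < 1L || length(ext$minima) < 1L) break
    env <- envelopes(h, ext$maxima, ext$minima)
    m <- (env$upper + env$lower) / 2
    h_new <- h - m
    sd_crit <- sum(m^2) / sum(h^2)
    h <- h_new
    if (sd_crit < sd_threshold) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a real time series into intrinsic mode functions (IMFs) by
#' iterative sifting. Each sift subtracts the mean of cubic-spline
#' envelopes through the local maxima and minima (mirror-extended by two
#' extrema at each end); an IMF is accepted when the Cauchy criterion
#' \eqn{SD = \sum (h_{prev}-h_{new})^2 / \sum h_{prev}^2} drops below
#' \code{sift_sd_threshold} or \code{max_sift} sifts have run.
#' Decomposition stops when the residual has fewer than two interior
#' extrema (i.e. is monotone). The decomposition is exactly additive:
#' the input equals the sum of IMFs plus the residual to floating
#' precision.
#'
#' @param x numeric vector, length >= 8, finite, non-constant.
#' @param max_sift maximum sifting iterations per IMF.
#' @param sift_sd_threshold Cauchy SD stopping threshold for sifting.
#' @param max_imf safety cap on the number of extracted IMFs.
#' @return An object of class \code{imf_set}: a list with \code{imfs}
#'   (list of numeric vectors, index 1 = highest frequency),
#'   \code{residual}, and \code{source_length}.
#' @examples
#' t <- seq_len(256)
#' z <- emd(sin(2 * pi * 0.1 * t) + 0.05 * t)
#' length(z$imfs)
#' @export
emd <- function(x, max_sift = 50L, sift_sd_threshold = 0.2, max_imf = 24L) {
  if (!is.numeric(x) || length(x) < 8L)
    stop_validation("emd() needs a numeric series of length >= 8 (got %d)",
                    length(x))
  if (any(!is.finite(x)))
    stop_validation("emd() input contains non-finite values")
  if (max(x) == min(x))
    stop_validation("emd() input is constant; no oscillatory content")
  if (sift_sd_threshold <= 0 || max_sift < 1)
    stop_validation("sifting thresholds must be positive")

  imfs <- list()
  r <- x
  amp_floor <- 1e-10 * (max(x) - min(x))  # numerical floor: residual is dust
  while (length(imfs) < max_imf) {
    if (max(r) - min(r) < amp_floor) break
    ext <- find_extrema(r)
    if (length(ext$maxima) + length(ext$minima) < 2L) break
    h <- sift_imf(r, max_sift, sift_sd_threshold)
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  structure(list(imfs = imfs, residual = r, source_length = length(x)),
            class = "imf_set")
}

#' EEMD parameter bundle
#'
#' @param ensemble_size number of noise-perturbed decompositions averaged
#'   (M). The canonical default is 100.
#' @param noise_amplitude standard deviation of the added white noise as a
#'   fraction of \code{sd(x)}; canonical default 0.2.
#' @param max_sift,sift_sd_threshold sifting controls, see [emd()].
#' @param min_support fraction of ensemble trials that must have produced
#'   an f-th IMF for the f-th averaged component to be emitted; components
#'   below this support are folded into the residual. Guards against
#'   vanishing-energy phantom tail components contributed by the few
#'   trials that decompose one level deeper than the rest.
#' @param seed RNG seed fixing the noise draws; required for reproducible
#'   ensembles.
#' @return list of class \code{eemd_params}.
#' @export
eemd_params <- function(ensemble_size = 100L, noise_amplitude = 0.2,
                        max_sift = 50L, sift_sd_threshold = 0.2,
                        min_support = 0.5, seed = NULL) {
  if (ensemble_size < 1L)
    stop_validation("ensemble_size must be >= 1")
  if (noise_amplitude < 0)
    stop_validation("noise_amplitude must be >= 0")
  if (max_sift < 1L || sift_sd_threshold <= 0)
    stop_validation("sifting thresholds must be positive")
  if (min_support <= 0 || min_support > 1)
    stop_validation("min_support must be in (0, 1]")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_amplitude = noise_amplitude,
                 max_sift = as.integer(max_sift),
                 sift_sd_threshold = sift_sd_threshold,
                 min_support = min_support,
                 seed = seed),
            class = "eemd_params")
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on \code{ensemble_size} copies of the input, each perturbed
#' with independent white noise of standard deviation
#' \code{noise_amplitude * sd(x)}, and averages the f-th IMF across trials.
#' Trials that produced fewer than f IMFs contribute zeros to the f-th
#' average, so no trial is discarded. Averaged components whose index is
#' reached by fewer than \code{min_support} of the trials are not emitted
#' (their mass stays in the residual): such components carry vanishing
#' energy and no interpretable frequency. The residual is defined as the
#' input minus the summed averaged IMFs, which keeps the decomposition
#' exactly additive.
#'
#' With \code{noise_amplitude = 0} and \code{ensemble_size = 1} the result
#' is identical to plain [emd()].
#'
#' @param x numeric series as in [emd()].
#' @param params an [eemd_params()] bundle.
#' @return An \code{imf_set} (see [emd()]) with attribute
#'   \code{ensemble_size}.
#' @export
eemd <- function(x, params = eemd_params()) {
  stopifnot(inherits(params, "eemd_params"))
  M <- params$ensemble_size
  amp <- params$noise_amplitude
  if (M == 1L && amp == 0) {
    out <- emd(x, params$max_sift, params$sift_sd_threshold)
    attr(out, "ensemble_size") <- 1L
    return(out)
  }
  n <- length(x)
  noise <- with_seed(params$seed,
                     matrix(stats::rnorm(n * M, sd = amp * stats::sd(x)),
                            nrow = n, ncol = M))
  trials <- lapply(seq_len(M), function(m)
    emd(x + noise[, m], params$max_sift, params$sift_sd_threshold)$imfs)
  counts <- vapply(trials, length, integer(1))
  support <- vapply(seq_len(max(counts)),
                    function(f) mean(counts >= f), numeric(1))
  n_imf <- max(which(support >= params$min_support))
  imfs <- lapply(seq_len(n_imf), function(f) {
    acc <- numeric(n)
    for (tr in trials) if (length(tr) >= f) acc <- acc + tr[[f]]
    acc / M
  })
  residual <- x - Reduce(`+`, imfs, numeric(n))
  structure(list(imfs = imfs, residual = residual, source_length = n),
            class = "imf_set", ensemble_size = M)
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s), T = %d\n",
              length(x$imfs), x$source_length))
  invisible(x)
}

#' Average frequency of a signal component
#'
#' Spectral centroid of the one-sided periodogram,
#' \eqn{\sum_k f_k P(f_k) / \sum_k P(f_k)} over \eqn{f \in (0, Nyquist]},
#' the summary used to order IMFs from high to low frequency. A
#' zero-crossing estimator (crossings / 2 per unit time) is available as an
#' alternative.
#'
#' @param imf numeric series, not identically zero.
#' @param TR sampling interval in seconds.
#' @param method \code{"centroid"} (default) or \code{"zero_crossing"}.
#' @return frequency in Hz.
#' @export
average_frequency <- function(imf, TR,
                              method = c("centroid", "zero_crossing")) {
  method <- match.arg(method)
  if (!is.numeric(imf) || length(imf) < 4L)
    stop_validation("average_frequency() needs a numeric series, length >= 4")
  if (all(imf == 0))
    stop_validation("average_frequency() undefined for an all-zero series")
  if (!is.numeric(TR) || TR <= 0)
    stop_validation("TR must be positive")
  n <- length(imf)
  if (method == "zero_crossing") {
    s <- sign(imf)
    s <- s[s != 0]
    crossings <- sum(diff(s) != 0)
    return(crossings / (2 * n * TR))
  }
  xc <- imf - mean(imf)
  pw <- Mod(stats::fft(xc))^2
  ks <- seq_len(floor(n / 2))          # one-sided bins, DC excluded
  f <- ks / (n * TR)
  p <- pw[ks + 1L]
  if (sum(p) == 0)
    stop_validation("average_frequency(): spectrum has no power off DC")
  sum(f * p) / sum(p)
}

#' Split per-ROI IMF sets into high- and low-frequency band signals
#'
#' The first IMF of every ROI forms the high-frequency band; the sum of
#' all remaining IMFs forms the low-frequency band. The residual trend is
#' excluded from the low band by default (it is a monotone drift, not an
#' oscillation) but can be folded in with \code{include_residual = TRUE}.
#' A ROI whose decomposition produced a single IMF yields an all-zero
#' low-band row and a warning.
#'
#' @param imfsets list of \code{imf_set} objects, one per ROI, all with the
#'   same source length.
#' @param include_residual fold the EMD residual into the low band.
#' @return An object of class \code{band_signals}: list with \code{high}
#'   and \code{low} (P x T matrices) and \code{residual} (P x T).
#' @export
split_bands <- function(imfsets, include_residual = FALSE) {
  if (length(imfsets) == 0L)
    stop_validation("split_bands() needs at least one ImfSet")
  ok <- vapply(imfsets, function(z)
    inherits(z, "imf_set") && length(z$imfs) >= 1L, logical(1))
  if (!all(ok))
    stop_validation("ROI(s) %s: empty or invalid ImfSet",
                    paste(which(!ok), collapse = ", "))
  P <- length(imfsets)
  T_len <- imfsets[[1L]]$source_length
  high <- matrix(0, P, T_len)
  low <- matrix(0, P, T_len)
  res <- matrix(0, P, T_len)
  single <- integer(0)
  for (i in seq_len(P)) {
    z <- imfsets[[i]]
    if (z$source_length != T_len)
      stop_validation("ROI %d has length %d, expected %d",
                      i, z$source_length, T_len)
    high[i, ] <- z$imfs[[1L]]
    if (length(z$imfs) >= 2L) {
      low[i, ] <- Reduce(`+`, z$imfs[-1L])
    } else {
      single <- c(single, i)
    }
    res[i, ] <- z$residual
  }
  if (include_residual) low <- low + res
  if (length(single))
    warning(sprintf("ROI(s) %s produced a single IMF; low band set to zero",
                    paste(single, collapse = ", ")))
  structure(list(high = high, low = low, residual = res),
            class = "band_signals")
}

#' Decompose every ROI signal of a subject into frequency bands
#'
#' Convenience wrapper: runs [eemd()] (or plain [emd()]) row-wise on a
#' P x T signal matrix and splits the IMFs into bands with [split_bands()].
#' Per-ROI noise seeds are derived deterministically from \code{params$seed}
#' so the decomposition is reproducible yet uses independent noise per ROI.
#'
#' @param X P x T matrix of ROI signals.
#' @param method \code{"eemd"} or \code{"emd"}.
#' @param params an [eemd_params()] bundle (ignored for \code{"emd"}
#'   except the sifting controls).
#' @param include_residual see [split_bands()].
#' @return A \code{band_signals} object.
#' @export
decompose_signals <- function(X, method = c("eemd", "emd"),
                              params = eemd_params(),
                              include_residual = FALSE) {
  method <- match.arg(method)
  if (!is.matrix(X)) stop_validation("X must be a P x T matrix")
  sets <- lapply(seq_len(nrow(X)), function(i) {
    if (method == "emd") {
      emd(X[i, ], params$max_sift, params$sift_sd_threshold)
    } else {
      p_i <- params
      if (!is.null(params$seed)) p_i$seed <- derive_seed(params$seed, i)
      eemd(X[i, ], p_i)
    }
  })
  split_bands(sets, include_residual = include_residual)
}
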