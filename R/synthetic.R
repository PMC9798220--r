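# Seeded synthetic cohorts with band-limited latent sources,
# community-structured per-band connectivity and planted group effects.
#
# Each ROI signal is the sum of a low-band component, a high-band component
# and white noise. Within each band, ROIs in the same community share a
# community latent with loading sqrt(within_corr), so the band-limited
# correlation between two same-community ROIs is within_corr and between
# communities 0. The group effect is planted by giving both ends of an
# effect edge an extra shared pair latent in the effect band with loading
# sqrt(effect_size), re-weighting (not adding) variance so all signals stay
# unit-variance: the target correlation on the edge shifts by effect_size
# in group 2 ("patient") relative to group 1 ("control").

#' Synthetic cohort specification
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults describe
#' a desk-scale resting-state-like cohort: 2 x 30 subjects, 20 ROIs, 137
#' time points at TR = 3 s, a low band of 0.015-0.06 Hz and a high band of
#' 0.06-0.15 Hz (the range conventional band-pass preprocessing retains,
#' split at the point separating the first intrinsic mode from the rest),
#' four communities per band with different partitions per band, and a
#' +0.4 correlation shift on five disjoint high-band edges in patients.
#'
#' @param n_per_group subjects per class.
#' @param P number of ROIs.
#' @param T_len time points per signal.
#' @param TR sampling interval, seconds.
#' @param low_band,high_band frequency intervals in Hz, each within
#'   (0, 1/(2 TR)); the low band must end where the high band begins or
#'   below.
#' @param communities_low,communities_high integer vectors of length P
#'   assigning each ROI to a community, per band.
#' @param effect_edges 2-column matrix of ROI pairs (i < j) carrying the
#'   group effect. Every connected component of the effect-edge graph
#'   must be a clique (disjoint pairs are the simplest case; a clique
#'   over m ROIs plants a distributed effect on all m(m-1)/2 edges of a
#'   subnetwork, the shape disease effects take in connectomics). Each
#'   component is driven by one shared latent, so the correlation shift
#'   is exactly \code{effect_size} on every component edge.
#' @param effect_band \code{"high"}, \code{"low"}, or \code{"both"}: band
#'   carrying the group difference. With \code{"both"} the effect edges
#'   alternate between the high and low band (odd-numbered edges high,
#'   even-numbered low), planting complementary effects.
#' @param effect_size target correlation shift on effect edges, in [0, 1].
#' @param within_corr baseline band-limited correlation within a
#'   community, in [0, 1].
#' @param noise_sd standard deviation of additive white noise.
#' @param seed RNG seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = 30L, P = 20L, T_len = 137L, TR = 3,
                        low_band = c(0.015, 0.06),
                        high_band = c(0.06, 0.15),
                        communities_low = NULL, communities_high = NULL,
                        effect_edges = NULL,
                        effect_band = c("high", "low", "both"),
                        effect_size = 0.4, within_corr = 0.6,
                        noise_sd = 0.5, seed = 1L) {
  effect_band <- match.arg(effect_band)
  P <- as.integer(P); T_len <- as.integer(T_len)
  if (P < 4L || T_len < 16L || n_per_group < 2L)
    stop_validation("cohort too small: need P >= 4, T >= 16, n >= 2")
  nyq <- 1 / (2 * TR)
  for (b in list(low = low_band, high = high_band)) {
    if (length(b) != 2L || b[1] <= 0 || b[2] > nyq || b[1] >= b[2])
      stop_validation("bands must be increasing intervals within (0, %.4g] Hz",
                      nyq)
  }
  if (low_band[2] > high_band[1])
    stop_validation("low_band max (%.3g) must be <= high_band min (%.3g)",
                    low_band[2], high_band[1])
  if (is.null(communities_low))                       # 4 consecutive blocks
    communities_low <- rep(seq_len(4L), each = ceiling(P / 4))[seq_len(P)]
  if (is.null(communities_high))                      # interleaved blocks
    communities_high <- rep_len(seq_len(4L), P)
  for (cm in list(communities_low, communities_high)) {
    if (length(cm) != P || anyNA(cm))
      stop_validation("community assignments must cover all %d ROIs", P)
    if (any(tabulate(match(cm, unique(cm))) == 0L))
      stop_validation("empty community in assignment")
  }
  if (is.null(effect_edges)) {
    n_pairs <- min(5L, P %/% 2L)          # up to 5 disjoint pairs
    effect_edges <- cbind(seq(1L, by = 2L, length.out = n_pairs),
                          seq(2L, by = 2L, length.out = n_pairs))
  }
  effect_edges <- as.matrix(effect_edges)
  storage.mode(effect_edges) <- "integer"
  if (ncol(effect_edges) != 2L ||
      any(effect_edges < 1L) || any(effect_edges > P) ||
      any(effect_edges[, 1L] >= effect_edges[, 2L]))
    stop_validation("effect_edges must be pairs (i, j) with 1 <= i < j <= P")
  components <- edge_components(effect_edges, P)
  for (nodes in components) {
    m <- length(nodes)
    n_in <- sum(effect_edges[, 1L] %in% nodes &
                effect_edges[, 2L] %in% nodes)
    if (n_in != m * (m - 1L) / 2L)
      stop_validation(paste0("effect-edge component {%s} is not a clique; ",
                             "each connected component must be complete"),
                      paste(nodes, collapse = ","))
  }
  if (effect_size < 0 || effect_size > 1)
    stop_validation("effect_size must be in [0, 1]")
  if (within_corr < 0 || within_corr > 1)
    stop_validation("within_corr must be in [0, 1]")
  if (within_corr + effect_size > 1)
    stop_validation(paste0("requested correlations unattainable: ",
                           "within_corr %.3g + effect_size %.3g > 1"),
                    within_corr, effect_size)
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  component_bands <- switch(effect_band,
    high = rep("high", length(components)),
    low = rep("low", length(components)),
    both = rep_len(c("high", "low"), length(components)))
  structure(list(n_per_group = as.integer(n_per_group), P = P,
                 T_len = T_len, TR = TR,
                 low_band = low_band, high_band = high_band,
                 communities_low = as.integer(communities_low),
                 communities_high = as.integer(communities_high),
                 effect_edges = effect_edges, effect_band = effect_band,
                 effect_components = components,
                 component_bands = component_bands,
                 effect_size = effect_size, within_corr = within_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Band-limited unit-variance latent series
#'
#' White Gaussian noise shaped by a hard FFT band mask: Fourier
#' coefficients outside \code{[band[1], band[2]]} Hz (and the DC bin) are
#' zeroed and the series is standardized to mean 0, sd 1. All periodogram
#' mass therefore lies inside the band by construction.
#'
#' @param T_len series length.
#' @param TR sampling interval, seconds.
#' @param band numeric length-2 interval in Hz, inside (0, 1/(2 TR)).
#' @param seed optional RNG seed.
#' @param n number of independent series (columns).
#' @return numeric vector (n = 1) or T x n matrix.
#' @export
generate_band_limited_latent <- function(T_len, TR, band, seed = NULL,
                                         n = 1L) {
  nyq <- 1 / (2 * TR)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop_validation("band must be an increasing interval above 0 Hz")
  if (band[2] > nyq)
    stop_validation("band [%.4g, %.4g] exceeds the Nyquist frequency %.4g Hz",
                    band[1], band[2], nyq)
  keep <- band_mask(T_len, TR, band)
  if (!any(keep))
    stop_validation("band [%.4g, %.4g] contains no DFT bin at T = %d, TR = %g",
                    band[1], band[2], T_len, TR)
  z <- with_seed(seed, matrix(stats::rnorm(T_len * n), T_len, n))
  out <- apply(z, 2L, function(col) {
    zf <- stats::fft(col)
    zf[!keep] <- 0
    s <- Re(stats::fft(zf, inverse = TRUE)) / T_len
    (s - mean(s)) / stats::sd(s)
  })
  if (n == 1L) drop(out) else out
}

# Logical mask over DFT bins whose frequency falls inside `band`,
# conjugate-symmetric, DC excluded.
band_mask <- function(T_len, TR, band) {
  f <- (seq_len(T_len) - 1) / (T_len * TR)
  half <- floor(T_len / 2)
  keep <- rep(FALSE, T_len)
  idx <- which(f >= band[1] & f <= band[2] & (seq_len(T_len) - 1) <= half)
  keep[idx] <- TRUE
  conj <- T_len - (idx - 1L) + 1L
  keep[conj[conj <= T_len]] <- TRUE
  keep[1L] <- FALSE
  keep
}

#' Band-pass filter signals with the generator's FFT mask
#'
#' Applies the same hard FFT band mask used by
#' [generate_band_limited_latent()] to each row of a P x T matrix. Used to
#' isolate one band of a mixed signal, e.g. when checking empirical
#' correlations against a cohort's ground-truth band networks.
#'
#' @param X P x T signal matrix (rows = ROIs).
#' @param band Hz interval.
#' @param TR sampling interval, seconds.
#' @return filtered P x T matrix.
#' @export
filter_band <- function(X, band, TR) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  keep <- band_mask(ncol(X), TR, band)
  t(apply(X, 1L, function(row) {
    zf <- stats::fft(row)
    zf[!keep] <- 0
    Re(stats::fft(zf, inverse = TRUE)) / ncol(X)
  }))
}

# Connected components of the effect-edge graph (union-find), returned as
# a list of sorted node vectors, ordered by smallest member.
edge_components <- function(edges, P) {
  parent <- seq_len(P)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(P), find, integer(1))
  touched <- sort(unique(as.vector(edges)))
  comp_ids <- unique(roots[touched])
  lapply(comp_ids, function(r) sort(touched[roots[touched] == r]))
}

# Per-band loading table for one group. Returns, for each ROI, the weights
# on (community latent, effect-component latent, idiosyncratic latent),
# plus which effect component each ROI belongs to in this band.
band_loadings <- function(spec, band, group) {
  P <- spec$P
  rho <- spec$within_corr
  eff <- spec$effect_size
  w <- matrix(0, P, 3L,
              dimnames = list(NULL, c("community", "pair", "idio")))
  w[, "community"] <- sqrt(rho)
  w[, "idio"] <- sqrt(1 - rho)
  comp_of <- rep(NA_integer_, P)
  if (group == 2L && eff > 0) {
    for (ci in which(spec$component_bands == band)) {
      nodes <- spec$effect_components[[ci]]
      w[nodes, "pair"] <- sqrt(eff)
      w[nodes, "idio"] <- sqrt(pmax(0, 1 - rho - eff))
      comp_of[nodes] <- ci
    }
  }
  attr(w, "comp_of") <- comp_of
  w
}

# Ground-truth band-limited correlation matrix for one band x group.
truth_matrix <- function(spec, band, group) {
  P <- spec$P
  comm <- if (band == "high") spec$communities_high else spec$communities_low
  W <- outer(comm, comm, `==`) * spec$within_corr
  if (group == 2L && spec$effect_size > 0) {
    for (ci in which(spec$component_bands == band)) {
      nodes <- spec$effect_components[[ci]]
      W[nodes, nodes] <- W[nodes, nodes] + spec$effect_size
    }
  }
  diag(W) <- 1
  W
}

#' Generate a synthetic cohort
#'
#' Draws \code{2 * n_per_group} subjects from the model described in
#' [cohort_spec()]. Group 1 subjects are labelled \code{"control"}, group 2
#' \code{"patient"}; patients differ only through the planted effect-edge
#' loadings in the effect band. The returned ground-truth matrices are the
#' target band-limited correlations (noise excluded).
#'
#' @param spec a [cohort_spec()].
#' @return An object of class \code{synthetic_cohort}: list with
#'   \code{subjects} (each a \code{roi_timeseries}: list of \code{values}
#'   P x T, \code{subject_id}, \code{label}, \code{TR}), \code{truth}
#'   (nested list \code{truth$high$patient} etc.), and \code{spec}.
#' @examples
#' co <- generate_cohort(cohort_spec(n_per_group = 3, P = 8, seed = 42))
#' dim(co$subjects[[1]]$values)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  P <- spec$P; T_len <- spec$T_len; TR <- spec$TR
  bands <- list(low = spec$low_band, high = spec$high_band)
  comms <- list(low = spec$communities_low, high = spec$communities_high)
  n_comp <- length(spec$effect_components)

  subjects <- with_seed(spec$seed, {
    out <- vector("list", 2L * spec$n_per_group)
    s_idx <- 0L
    for (group in 1:2) {
      for (subj in seq_len(spec$n_per_group)) {
        X <- matrix(0, P, T_len)
        for (bn in names(bands)) {
          comm <- comms[[bn]]
          n_comm <- length(unique(comm))
          L <- cbind(generate_band_limited_latent(T_len, TR, bands[[bn]],
                                                  n = n_comm))
          Q <- if (n_comp > 0L)
            cbind(generate_band_limited_latent(T_len, TR, bands[[bn]],
                                               n = n_comp))
          I <- cbind(generate_band_limited_latent(T_len, TR, bands[[bn]],
                                                  n = P))
          w <- band_loadings(spec, bn, group)
          comp_of <- attr(w, "comp_of")
          for (i in seq_len(P)) {
            s <- w[i, "community"] * L[, match(comm[i], unique(comm))] +
                 w[i, "idio"] * I[, i]
            if (w[i, "pair"] > 0) s <- s + w[i, "pair"] * Q[, comp_of[i]]
            X[i, ] <- X[i, ] + s
          }
        }
        if (spec$noise_sd > 0)
          X <- X + matrix(stats::rnorm(P * T_len, sd = spec$noise_sd),
                          P, T_len)
        s_idx <- s_idx + 1L
        out[[s_idx]] <- structure(
          list(values = X,
               subject_id = sprintf("S%03d", s_idx),
               label = if (group == 1L) "control" else "patient",
               TR = TR),
          class = "roi_timeseries")
      }
    }
    out
  })

  truth <- list(
    low = list(control = truth_matrix(spec, "low", 1L),
               patient = truth_matrix(spec, "low", 2L)),
    high = list(control = truth_matrix(spec, "high", 1L),
                patient = truth_matrix(spec, "high", 2L)))
  structure(list(subjects = subjects, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("<synthetic_cohort> %d subjects (%d/group), P = %d, ",
                     "T = %d, TR = %gs\n  effect: %+.2f on %d %s-band ",
                     "edge(s), noise sd %.2f, seed %d\n"),
              2 * s$n_per_group, s$n_per_group, s$P, s$T_len, s$TR,
              s$effect_size, nrow(s$effect_edges), s$effect_band,
              s$noise_sd, s$seed))
  invisible(x)
}

#' Cohort labels as a character vector
#'
#' @param cohort a \code{synthetic_cohort} or list of \code{roi_timeseries}.
#' @return character vector of labels, one per subject.
#' @export
cohort_labels <- function(cohort) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  vapply(subjects, function(s) s$label, character(1))
}
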