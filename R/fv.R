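# Per-ROI frequency variability: how much a region's connectivity profile
# differs across frequency-band networks.

#' Frequency variability of each ROI across band networks
#'
#' For node i, let \eqn{FC_{f,i}} be column i of the band-f network with
#' the diagonal entry removed (its connectivity profile to the other
#' ROIs). Frequency variability is one minus the mean Pearson correlation
#' of these profiles over all unordered band pairs:
#' \deqn{FV_i = 1 - \mathrm{mean}_{f<g}\ \mathrm{corr}(FC_{f,i}, FC_{g,i}).}
#' With two bands this reduces to \eqn{1 - corr(FC_{high,i}, FC_{low,i})},
#' so identical band networks give 0 and sign-flipped ones give 2; larger
#' values mean the region's connectivity changes more across bands.
#'
#' @param networks list of >= 2 symmetric P x P band networks.
#' @param band_labels optional names for the bands (defaults to list
#'   names or \code{band1, band2, ...}).
#' @return numeric vector of length P with attributes \code{n_bands} and
#'   \code{band_labels}. A ROI whose profile has zero variance in some
#'   band yields \code{NA} and a warning naming the ROI.
#' @export
frequency_variability <- function(networks, band_labels = NULL) {
  if (!is.list(networks) || length(networks) < 2L)
    stop_validation("frequency_variability() needs >= 2 band networks")
  P <- nrow(networks[[1L]])
  for (W in networks) {
    check_symmetric(W, what = "band network")
    if (nrow(W) != P)
      stop_validation("band networks have mismatched sizes (%d vs %d)",
                      P, nrow(W))
  }
  if (is.null(band_labels))
    band_labels <- names(networks) %||%
      paste0("band", seq_along(networks))
  n_b <- length(networks)
  pairs <- utils::combn(n_b, 2L)
  fv <- numeric(P)
  degenerate <- integer(0)
  for (i in seq_len(P)) {
    profiles <- vapply(networks, function(W) unclass(W)[-i, i], numeric(P - 1L))
    if (any(apply(profiles, 2L, stats::sd) == 0)) {
      fv[i] <- NA_real_
      degenerate <- c(degenerate, i)
      next
    }
    cors <- apply(pairs, 2L, function(pr)
      stats::cor(profiles[, pr[1L]], profiles[, pr[2L]]))
    fv[i] <- 1 - mean(cors)
  }
  if (length(degenerate))
    warning(sprintf("FV undefined for ROI(s) %s (zero-variance profile)",
                    paste(degenerate, collapse = ", ")))
  names(fv) <- paste0("ROI", seq_len(P))
  structure(fv, n_bands = n_b, band_labels = band_labels)
}
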