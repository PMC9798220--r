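# Similarity network fusion: KNN-sparsified affinity kernels and the
# cross-diffusion iteration that blends the high- and low-band networks
# into one fused matrix, plus the feature-concatenation baseline.

#' KNN-sparsified similarity kernel
#'
#' Builds the local affinity kernel S from a connectivity matrix: the
#' affinity is the absolute edge weight (diffusion requires non-negative
#' affinities; magnitude preserves the strength of both positive and
#' negative correlations), and for each column j only the k strongest
#' neighbors \eqn{i \in KNN_j} keep their affinity, all other entries are
#' set to zero. Ties at rank k are all retained, making the kernel
#' deterministic. The diagonal is zero.
#'
#' @param W symmetric connectivity matrix.
#' @param k neighbor count, 1 <= k <= P - 1.
#' @return matrix of class \code{similarity_kernel} with attribute
#'   \code{k}.
#' @export
knn_kernel <- function(W, k) {
  check_symmetric(W, what = "network")
  P <- nrow(W)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > P - 1L)
    stop_validation("k must satisfy 1 <= k <= P - 1 (P = %d)", P)
  k <- as.integer(k)
  A <- abs(unclass(W))
  diag(A) <- 0
  S <- matrix(0, P, P)
  for (j in seq_len(P)) {
    col <- A[, j]
    col[j] <- -Inf
    cutoff <- sort(col, decreasing = TRUE)[k]
    keep <- which(col >= cutoff)
    S[keep, j] <- A[keep, j]
  }
  structure(S, class = c("similarity_kernel", class(S)), k = k)
}

#' Fuse two band networks by similarity network fusion
#'
#' Cross-diffusion of the high- and low-band networks through their
#' KNN-sparsified kernels. Writing \eqn{A_v = |W_v|} (diagonal zeroed) and
#' \eqn{S_v} for the KNN kernel of band v, the iteration updates both
#' status matrices simultaneously,
#' \deqn{P_{high} \leftarrow S_{high} P_{low} S_{high}^T , \quad
#'       P_{low} \leftarrow S_{low} P_{high} S_{low}^T ,}
#' each product symmetrized as \eqn{(M + M^T)/2}, and stops when the
#' Frobenius-norm change of both matrices is at most \code{tol} (or at
#' \code{max_iter}). The fused network is the elementwise average of the
#' two final iterates with zeroed diagonal.
#'
#' Two normalization modes are provided. \code{"normalized"} (default)
#' uses the lazy-diffusion normalization of canonical SNF: the KNN
#' kernels are row-normalized, and the status matrices are normalized as
#' \eqn{P \leftarrow P / (2\,\mathrm{rowSums}(P)) + I/2} at
#' initialization and after every update, keeping half of each node's
#' diffusion mass on itself. This anchors the iteration (bare
#' simultaneous cross-updates oscillate rather than converge) and keeps
#' row sums at 1. \code{"literal"} iterates the raw products with no
#' normalization, which reproduces the bare update rule exactly (useful
#' for checking the algebra on small examples) but can shrink or inflate
#' scales.
#'
#' @param w_high,w_low symmetric P x P connectivity matrices for the two
#'   bands.
#' @param k neighbor count for the KNN kernels (default 11, the framework
#'   setting).
#' @param tol Frobenius-change stopping threshold (default 0.01), applied
#'   to both matrices.
#' @param max_iter iteration cap.
#' @param mode \code{"normalized"} or \code{"literal"}.
#' @return \code{connectivity_matrix} of kind \code{"fused"} with
#'   attributes \code{iterations}, \code{converged}, \code{delta_high},
#'   \code{delta_low}, \code{k} and \code{mode}. Non-convergence at
#'   \code{max_iter} yields \code{converged = FALSE} plus a warning; the
#'   last iterate average is still returned.
#' @export
snf_fuse <- function(w_high, w_low, k = 11L, tol = 0.01, max_iter = 100L,
                     mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  check_symmetric(w_high, what = "w_high")
  check_symmetric(w_low, what = "w_low")
  if (nrow(w_high) != nrow(w_low))
    stop_validation("w_high is %d x %d but w_low is %d x %d",
                    nrow(w_high), ncol(w_high), nrow(w_low), ncol(w_low))
  A_h <- abs(unclass(w_high)); diag(A_h) <- 0
  A_l <- abs(unclass(w_low));  diag(A_l) <- 0
  S_h <- unclass(knn_kernel(w_high, k))
  S_l <- unclass(knn_kernel(w_low, k))
  lazy_normalize <- function(M) {        # canonical SNF status normalization
    M <- row_normalize(M) / 2
    diag(M) <- diag(M) + 0.5
    (M + t(M)) / 2
  }
  if (mode == "normalized") {
    P_h <- lazy_normalize(A_h); P_l <- lazy_normalize(A_l)
    # the KNN kernel lists node j's neighborhood in column j; diffusion
    # averages over each node's own neighborhood, so orient neighborhoods
    # along rows before row-normalizing
    S_h <- row_normalize(t(S_h)); S_l <- row_normalize(t(S_l))
  } else {
    P_h <- A_h; P_l <- A_l
  }
  converged <- FALSE
  d_h <- d_l <- NA_real_
  g <- 0L
  while (g < max_iter) {
    g <- g + 1L
    P_h_new <- S_h %*% P_l %*% t(S_h)
    P_l_new <- S_l %*% P_h %*% t(S_l)      # uses the previous P_h
    P_h_new <- (P_h_new + t(P_h_new)) / 2
    P_l_new <- (P_l_new + t(P_l_new)) / 2
    if (mode == "normalized") {
      P_h_new <- lazy_normalize(P_h_new)
      P_l_new <- lazy_normalize(P_l_new)
    }
    d_h <- frobenius_norm(P_h_new - P_h)
    d_l <- frobenius_norm(P_l_new - P_l)
    P_h <- P_h_new; P_l <- P_l_new
    if (d_h <= tol && d_l <= tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf(
      "SNF did not converge in %d iterations (deltas %.3g / %.3g > %.3g)",
      max_iter, d_h, d_l, tol))
  fused <- (P_h + P_l) / 2
  diag(fused) <- 0
  out <- connectivity_matrix(fused, kind = "fused", band = "fused")
  attr(out, "iterations") <- g
  attr(out, "converged") <- converged
  attr(out, "delta_high") <- d_h
  attr(out, "delta_low") <- d_l
  attr(out, "k") <- as.integer(k)
  attr(out, "mode") <- mode
  out
}

#' Concatenation baseline for band fusion
#'
#' The non-fused alternative: the upper-triangle edge vectors of the two
#' band networks are spliced into one feature vector of length
#' \eqn{2 P (P-1) / 2}, high band first.
#'
#' @param w_high,w_low symmetric P x P connectivity matrices.
#' @return numeric vector of length \code{P * (P - 1)}.
#' @export
concatenate_baseline <- function(w_high, w_low) {
  if (nrow(w_high) != nrow(w_low) || ncol(w_high) != ncol(w_low))
    stop_validation("band networks must have matching dimensions")
  c(edge_vector(w_high), edge_vector(w_low))
}
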