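# Functional brain network estimation: signal normalization, Pearson
# correlation networks with magnitude thresholding, and sparse
# representation (node-wise lasso) networks.

#' Construct a connectivity matrix object
#'
#' Lightweight S3 wrapper around a symmetric P x P matrix carrying the
#' estimator kind and frequency band as attributes. Pearson networks must
#' have unit diagonal and entries in [-1, 1]; sparse-representation and
#' fused networks have zero diagonal.
#'
#' @param values symmetric P x P numeric matrix.
#' @param kind \code{"pc"}, \code{"sr"} or \code{"fused"}.
#' @param band \code{"high"}, \code{"low"}, \code{"full"} or \code{"fused"}.
#' @param sparsity_applied fraction of edges retained by thresholding, or
#'   \code{NA} if none.
#' @return matrix of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(values, kind = c("pc", "sr", "fused"),
                                band = c("full", "high", "low", "fused"),
                                sparsity_applied = NA_real_) {
  kind <- match.arg(kind)
  band <- match.arg(band)
  check_symmetric(values, tol = 1e-9, what = "connectivity matrix")
  values <- (values + t(values)) / 2     # exact symmetry for downstream use
  if (kind == "pc") {
    if (max(abs(values)) > 1 + 1e-9)
      stop_validation("pc entries must lie in [-1, 1]")
    if (max(abs(diag(values) - 1)) > 1e-9)
      stop_validation("pc diagonal must be 1")
  } else if (max(abs(diag(values))) > 1e-9) {
    stop_validation("%s diagonal must be 0", kind)
  }
  structure(values, class = c("connectivity_matrix", class(values)),
            kind = kind, band = band, sparsity_applied = sparsity_applied)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s/%s, P = %d, sparsity = %s\n",
              attr(x, "kind"), attr(x, "band"), nrow(x),
              format(attr(x, "sparsity_applied"))))
  invisible(x)
}

#' Standardize ROI signals to zero mean, unit variance
#'
#' Row-wise standardization \eqn{r(x) = (x - \mu_i) / \sigma_i}, the
#' normalization applied to every ROI signal before network estimation.
#'
#' @param X P x T matrix, rows = ROI signals, each non-constant.
#' @return P x T matrix with row means 0 and row standard deviations 1.
#' @export
normalize_roi_signals <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop_validation("X must be a numeric P x T matrix")
  if (anyNA(X)) stop_validation("X contains missing values")
  mu <- rowMeans(X)
  sdv <- apply(X, 1L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop_validation("ROI(s) %s have zero variance and cannot be normalized",
                    paste(bad, collapse = ", "))
  (X - mu) / sdv
}

#' Pearson correlation network
#'
#' Full-rank functional connectivity: \eqn{W_{ij}} is the Pearson
#' correlation of the i-th and j-th ROI signals (centered inner product
#' over the product of centered norms).
#'
#' @param X P x T matrix of ROI signals, each row non-constant.
#' @param band band label recorded on the result.
#' @return \code{connectivity_matrix} of kind \code{"pc"} with unit
#'   diagonal.
#' @export
pearson_network <- function(X, band = "full") {
  if (!is.matrix(X) || nrow(X) < 2L || ncol(X) < 3L)
    stop_validation("X must be a P x T matrix with P >= 2, T >= 3")
  sdv <- apply(X, 1L, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop_validation("ROI(s) %s are constant; correlation undefined",
                    paste(bad, collapse = ", "))
  W <- stats::cor(t(X))
  diag(W) <- 1
  connectivity_matrix(W, kind = "pc", band = band)
}

#' Keep only the strongest edges of a network
#'
#' Retains the \code{keep_fraction} of upper-triangle edges with the
#' largest absolute weight and zeroes the rest; the cutoff is the
#' magnitude of the \code{ceiling(keep_fraction * E)}-th largest edge and
#' ties at the cutoff are all retained. The diagonal is untouched and
#' \code{keep_fraction = 1} returns the network unchanged.
#'
#' @param W symmetric connectivity matrix.
#' @param keep_fraction fraction of edges to retain, in (0, 1].
#' @return thresholded \code{connectivity_matrix} with
#'   \code{sparsity_applied = keep_fraction}.
#' @export
threshold_network <- function(W, keep_fraction) {
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1)
    stop_validation("keep_fraction must be in (0, 1]")
  check_symmetric(W, what = "network")
  V <- unclass(W)
  # infer the estimator kind for plain matrices from the diagonal
  kind <- attr(W, "kind") %||%
    (if (max(abs(diag(V) - 1)) <= 1e-9) "pc" else "sr")
  band <- attr(W, "band") %||% "full"
  ut <- upper.tri(V)
  mags <- abs(V[ut])
  n_keep <- ceiling(keep_fraction * length(mags))
  cutoff <- sort(mags, decreasing = TRUE)[n_keep]
  drop_mask <- ut & (abs(V) < cutoff)
  V[drop_mask | t(drop_mask)] <- 0
  out <- connectivity_matrix(V, kind = kind, band = band,
                             sparsity_applied = keep_fraction)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cyclic coordinate descent for min ||y - A w||^2 + lambda * sum |w|,
# on precomputed Gram quantities G = A'A, b = A'y. Returns the solution
# and the attained KKT violation.
lasso_cd <- function(G, b, lambda, tol = 1e-6, max_sweeps = 10000L) {
  p <- length(b)
  w <- numeric(p)
  q <- numeric(p)               # q = G w
  gd <- diag(G)
  half <- lambda / 2
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(p)) {
      cj <- b[j] - q[j] + gd[j] * w[j]
      wj <- sign(cj) * max(abs(cj) - half, 0) / gd[j]
      if (wj != w[j]) {
        q <- q + G[, j] * (wj - w[j])
        w[j] <- wj
      }
    }
    grad <- b - q
    viol <- ifelse(w == 0, pmax(abs(grad) - half, 0),
                   abs(grad - half * sign(w)))
    kkt <- max(viol)
    if (kkt <= tol) break
  }
  list(w = w, kkt = kkt, sweeps = sweep)
}

#' Sparse representation (node-wise lasso) network
#'
#' Regresses each ROI signal on all other ROI signals under an l1 penalty:
#' for each node i it solves
#' \deqn{\min_{w} \|x_i - \sum_{j \ne i} w_j x_j\|^2 + \lambda \sum_{j \ne i} |w_j|}
#' by cyclic coordinate descent (KKT tolerance \code{tol}), then
#' symmetrizes the coefficient matrix as \eqn{(W + W^T)/2}. The penalty
#' multiplies the l1 term directly (no 1/2T scaling), so \code{lambda}
#' values are comparable across series lengths only for standardized
#' signals; rows are standardized internally (a no-op when already
#' normalized).
#'
#' @param X P x T matrix of ROI signals.
#' @param lambda positive l1 penalty weight.
#' @param tol KKT violation tolerance for the coordinate descent.
#' @param max_sweeps cap on full coordinate sweeps per node.
#' @param band band label recorded on the result.
#' @return \code{connectivity_matrix} of kind \code{"sr"} with zero
#'   diagonal and attribute \code{lambda}. If any node fails to reach
#'   \code{tol} a warning reports the worst attained violation.
#' @export
sparse_representation_network <- function(X, lambda, tol = 1e-6,
                                          max_sweeps = 10000L,
                                          band = "full") {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop_validation("lambda must be a positive scalar")
  X <- normalize_roi_signals(X)
  P <- nrow(X)
  G_full <- X %*% t(X)
  W <- matrix(0, P, P)
  worst <- 0
  for (i in seq_len(P)) {
    idx <- setdiff(seq_len(P), i)
    fit <- lasso_cd(G_full[idx, idx, drop = FALSE], G_full[idx, i],
                    lambda, tol = tol, max_sweeps = max_sweeps)
    W[i, idx] <- fit$w
    worst <- max(worst, fit$kkt)
  }
  if (worst > tol)
    warning(sprintf(
      "coordinate descent stopped at KKT violation %.3g (tol %.3g)",
      worst, tol))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  out <- connectivity_matrix(W, kind = "sr", band = band)
  attr(out, "lambda") <- lambda
  attr(out, "kkt") <- worst
  out
}
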