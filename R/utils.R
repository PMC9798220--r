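# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. A NULL seed leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays below .Machine$integer.max.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 7919 + as.numeric(p) + 1) %% 2147483629
  as.integer(s)
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("mbnf_validation_error", "error")))
}

frobenius_norm <- function(M) sqrt(sum(M^2))

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

check_symmetric <- function(M, tol = 1e-9, what = "matrix") {
  if (!is_square(M)) stop_validation("%s must be square", what)
  dev <- max(abs(M - t(M)))
  if (dev > tol)
    stop_validation("%s is asymmetric (max deviation %.3g > %.3g)",
                    what, dev, tol)
  invisible(dev)
}

# Coerce labels to a 0/1 vector with patient (positive class) = 1.
# Accepts factors/characters containing "patient"/"control", logicals,
# or numeric 0/1; otherwise the second sorted unique value is positive.
binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1)))
      stop_validation("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  u <- sort(unique(labels))
  if (length(u) != 2L)
    stop_validation("labels must contain exactly 2 classes, got %d",
                    length(u))
  pos <- if ("patient" %in% u) "patient" else u[2L]
  as.integer(labels == pos)
}

row_normalize <- function(M) {
  rs <- rowSums(M)
  rs[rs == 0] <- 1
  M / rs
}
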