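# Edge features, t-test feature selection, SVM classification under
# repeated nested cross-validation, classification metrics, method
# comparison and the network-noise robustness experiment.

#' Upper-triangle edge index map
#'
#' @param P number of ROIs.
#' @return integer matrix with columns \code{i}, \code{j} listing the
#'   \code{P(P-1)/2} upper-triangle pairs (i < j) in row-major order:
#'   (1,2), (1,3), ..., (1,P), (2,3), ...
#' @export
edge_index <- function(P) {
  i <- rep.int(seq_len(P - 1L), times = (P - 1L):1L)
  j <- unlist(lapply(seq_len(P - 1L), function(a) (a + 1L):P))
  cbind(i = i, j = j)
}

#' Vectorize a symmetric network's upper triangle
#'
#' Maps a symmetric P x P matrix to its \code{P(P-1)/2} upper-triangle
#' entries in the row-major order of [edge_index()], the edge-feature
#' representation used for classification.
#'
#' @param W symmetric matrix (asymmetry beyond 1e-9 is rejected).
#' @return numeric vector of length \code{P(P-1)/2}.
#' @export
edge_vector <- function(W) {
  check_symmetric(W, tol = 1e-9, what = "network")
  V <- unclass(W)
  tV <- t(V)
  tV[lower.tri(tV)]
}

#' Stack per-subject networks into an edge-feature matrix
#'
#' @param networks list of symmetric P x P matrices, one per subject.
#' @return N x E matrix, E = P(P-1)/2, rows ordered as \code{networks}.
#' @export
edge_feature_matrix <- function(networks) {
  feats <- t(vapply(networks, edge_vector,
                    numeric(nrow(networks[[1L]]) *
                            (nrow(networks[[1L]]) - 1L) / 2)))
  feats
}

#' Two-sample t-test edge selection
#'
#' Per-edge two-sample t-test between the classes of the training
#' subjects; edges with p below \code{alpha} are selected. No
#' multiple-testing correction is applied (the selection feeds a
#' classifier, it is not an inference). Pooled-variance t by default;
#' Welch via \code{var_equal = FALSE}. Edges with zero variance in both
#' groups are excluded with a warning.
#'
#' @param features N x E edge-feature matrix (training subjects only).
#' @param labels length-N labels; "patient" (or 1) is the positive class.
#' @param alpha selection threshold on p (default 0.05).
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return list with \code{mask} (logical length E), \code{t}, \code{p}.
#' @export
ttest_select <- function(features, labels, alpha = 0.05,
                         var_equal = TRUE) {
  y <- binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop_validation("t-test selection needs both classes in the training set")
  if (nrow(features) != length(y))
    stop_validation("features and labels disagree on N")
  g1 <- features[y == 1L, , drop = FALSE]
  g0 <- features[y == 0L, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- colSums((g1 - rep(m1, each = n1))^2) / (n1 - 1L)
  v0 <- colSums((g0 - rep(m0, each = n0))^2) / (n0 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n0 - 1L) * v0) / (n1 + n0 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v0 / n0)^2 / (n0 - 1L))
  }
  tt <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tt), df)
  dead <- which(v1 == 0 & v0 == 0)
  if (length(dead)) {
    p[dead] <- NA_real_
    tt[dead] <- NA_real_
    warning(sprintf("%d edge(s) with zero variance in both groups excluded",
                    length(dead)))
  }
  mask <- !is.na(p) & p < alpha
  list(mask = mask, t = tt, p = p)
}

#' Classification metrics from confusion counts
#'
#' \deqn{ACC = (TP+TN)/(TP+FP+TN+FN) \cdot 100,\quad
#'       SEN = TP/(TP+FN) \cdot 100,\quad
#'       SPE = TN/(TN+FP) \cdot 100.}
#' Patients are the positive class.
#'
#' @param tp,tn,fp,fn non-negative integer confusion counts.
#' @return named numeric vector \code{c(acc, sen, spe)} in percent; a
#'   metric whose denominator is empty is \code{NA} with a warning.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("confusion counts must be non-negative integers")
  n <- tp + tn + fp + fn
  if (n == 0L) stop_validation("empty confusion table")
  acc <- (tp + tn) / n * 100
  sen <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  if (anyNA(c(sen, spe)))
    warning("a class is absent from the test set; SEN or SPE undefined")
  c(acc = acc, sen = sen, spe = spe)
}

# Stratified k-fold assignment; returns an integer fold id per subject.
# Each class is shuffled and dealt round-robin, so folds are balanced to
# within one subject per class.
stratified_folds <- function(y, k, seed = NULL) {
  if (min(table(y)) < k)
    stop_validation("cannot stratify: a class has fewer than %d subjects", k)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Fit a linear SVM on selected features and score a test set. Returns
# predictions (0/1) and a decision score oriented so larger = more
# patient-like.
fit_svm <- function(x_train, y_train, x_test, cost = 1) {
  yf <- factor(y_train, levels = c(0L, 1L))
  m <- e1071::svm(x_train, yf, kernel = "linear", cost = cost,
                  scale = FALSE)
  pr <- stats::predict(m, x_test, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  # e1071 orients the decision value toward the first class in its header
  pos_first <- startsWith(colnames(attr(pr, "decision.values"))[1L], "1")
  score <- if (pos_first) dv else -dv
  list(pred = as.integer(as.character(pr)), score = score)
}

# Mean inner-CV accuracy of one candidate feature set.
inner_cv_accuracy <- function(features, y, folds, alpha, cost) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    sel <- suppressWarnings(ttest_select(features[tr, , drop = FALSE],
                                         y[tr], alpha = alpha))
    keep <- selected_columns(sel)
    fit <- fit_svm(features[tr, keep, drop = FALSE], y[tr],
                   features[!tr, keep, drop = FALSE], cost = cost)
    mean(fit$pred == y[!tr])
  }, numeric(1))
  mean(accs)
}

# Column indices used for classification: the selected mask, or the
# single smallest-p edge if the mask is empty (an SVM needs >= 1 input).
selected_columns <- function(sel) {
  if (any(sel$mask)) which(sel$mask) else which.min(sel$p)
}

#' Repeated nested cross-validated SVM classification
#'
#' The evaluation protocol of the framework: stratified 5-fold outer CV,
#' repeated \code{n_repeats} times with fresh seeded splits. Within each
#' outer training set an inner stratified 5-fold CV picks the
#' hyperparameter (a network sparsity or lasso penalty; one edge-feature
#' matrix per candidate value) maximizing mean inner accuracy, ties going
#' to the smaller value. The winning feature set is then t-test-filtered
#' on the outer training subjects only and a linear SVM (default C = 1)
#' is trained and applied to the held-out fold. Per repeat, confusion
#' counts pool over the 5 folds and AUC is computed from the pooled
#' decision scores; means and standard deviations over repeats are
#' reported. Feature selection and hyperparameter choice never see test
#' subjects.
#'
#' @param features_by_grid named list of N x E edge-feature matrices, one
#'   per hyperparameter candidate (a single matrix is treated as a
#'   one-point grid).
#' @param labels length-N labels; "patient" (or 1) is positive.
#' @param grid numeric hyperparameter values aligned with
#'   \code{features_by_grid} (defaults to its names).
#' @param n_repeats number of repeated CV rounds (default 10).
#' @param n_folds outer and inner fold count (default 5).
#' @param seed master seed; repeat r uses a seed derived from it.
#' @param alpha t-test selection threshold.
#' @param cost SVM regularization C.
#' @return An object of class \code{cv_report}: list with
#'   \code{acc_mean}, \code{acc_sd}, \code{sen_mean}, \code{sen_sd},
#'   \code{spe_mean}, \code{spe_sd}, \code{auc_mean}, \code{auc_sd} (all
#'   percentages), \code{per_repeat} (repeat x metric matrix),
#'   \code{chosen} (repeat x fold matrix of grid values),
#'   \code{n_repeats}, \code{n_folds}, \code{seed}.
#' @export
nested_cv_classify <- function(features_by_grid, labels, grid = NULL,
                               n_repeats = 10L, n_folds = 5L, seed = 1L,
                               alpha = 0.05, cost = 1) {
  if (is.matrix(features_by_grid))
    features_by_grid <- list(features_by_grid)
  if (length(features_by_grid) == 0L)
    stop_validation("empty hyperparameter grid")
  if (is.null(grid)) {
    grid <- suppressWarnings(as.numeric(names(features_by_grid)))
    if (length(grid) == 0L || anyNA(grid))
      grid <- seq_along(features_by_grid)
  }
  ord <- order(grid)                      # ties break toward smaller value
  grid <- grid[ord]
  features_by_grid <- features_by_grid[ord]
  y <- binary_labels(labels)
  n <- length(y)
  if (min(table(y)) < 10L)
    warning("fewer than 10 subjects in a class; estimates will be unstable")

  metrics <- matrix(NA_real_, n_repeats, 4L,
                    dimnames = list(NULL, c("acc", "sen", "spe", "auc")))
  chosen <- matrix(NA_real_, n_repeats, n_folds)
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(y, n_folds, seed = derive_seed(seed, r))
    conf <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    scores <- numeric(n)
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (length(grid) > 1L) {
        inner <- stratified_folds(y[tr], n_folds,
                                  seed = derive_seed(seed, r, f))
        inner_acc <- vapply(seq_along(grid), function(gi)
          inner_cv_accuracy(features_by_grid[[gi]][tr, , drop = FALSE],
                            y[tr], inner, alpha, cost), numeric(1))
        best <- which.max(inner_acc)      # first max = smallest grid value
      } else {
        best <- 1L
      }
      chosen[r, f] <- grid[best]
      feats <- features_by_grid[[best]]
      sel <- suppressWarnings(ttest_select(feats[tr, , drop = FALSE],
                                           y[tr], alpha = alpha))
      keep <- selected_columns(sel)
      fit <- fit_svm(feats[tr, keep, drop = FALSE], y[tr],
                     feats[!tr, keep, drop = FALSE], cost = cost)
      yt <- y[!tr]
      conf <- conf + c(tp = sum(fit$pred == 1L & yt == 1L),
                       tn = sum(fit$pred == 0L & yt == 0L),
                       fp = sum(fit$pred == 1L & yt == 0L),
                       fn = sum(fit$pred == 0L & yt == 1L))
      scores[!tr] <- fit$score
    }
    m <- suppressWarnings(
      confusion_metrics(conf["tp"], conf["tn"], conf["fp"], conf["fn"]))
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = scores, levels = c(0L, 1L),
      direction = "<", quiet = TRUE))) * 100
    metrics[r, ] <- c(m, auc)
  }
  structure(list(
    acc_mean = mean(metrics[, "acc"]), acc_sd = stats::sd(metrics[, "acc"]),
    sen_mean = mean(metrics[, "sen"]), sen_sd = stats::sd(metrics[, "sen"]),
    spe_mean = mean(metrics[, "spe"]), spe_sd = stats::sd(metrics[, "spe"]),
    auc_mean = mean(metrics[, "auc"]), auc_sd = stats::sd(metrics[, "auc"]),
    per_repeat = metrics, chosen = chosen,
    n_repeats = n_repeats, n_folds = n_folds, seed = seed),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(paste0("<cv_report> %d x %d-fold CV\n",
                     "  ACC %5.2f +/- %.2f   SEN %5.2f +/- %.2f\n",
                     "  SPE %5.2f +/- %.2f   AUC %5.2f +/- %.2f\n"),
              x$n_repeats, x$n_folds,
              x$acc_mean, x$acc_sd, x$sen_mean, x$sen_sd,
              x$spe_mean, x$spe_sd, x$auc_mean, x$auc_sd))
  invisible(x)
}

#' Paired t-test between two methods' per-repeat accuracies
#'
#' Two-sided paired t-test on per-repeat metric differences from the same
#' CV splits (pair repeats by seed).
#'
#' @param metric_a,metric_b numeric vectors of equal length >= 2, one
#'   entry per repeat.
#' @param alpha significance level for the flag.
#' @return list with \code{p_value}, \code{significant}, and
#'   \code{mean_diff} (a - b). Zero-variance differences give
#'   \code{p_value = NA} and \code{significant = FALSE}.
#' @export
paired_ttest_compare <- function(metric_a, metric_b, alpha = 0.05) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2L)
    stop_validation("need paired vectors of equal length >= 2")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    return(list(p_value = NA_real_, significant = FALSE,
                mean_diff = mean(d),
                note = "zero-variance differences; t undefined"))
  }
  ht <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(p_value = ht$p.value, significant = ht$p.value < alpha,
       mean_diff = mean(d))
}

#' Robustness of classification to network-level noise
#'
#' Adds symmetric white Gaussian noise of increasing standard deviation to
#' every subject's connectivity matrix (noise drawn on the upper triangle
#' and mirrored, so matrices stay symmetric) and re-runs the
#' classification pipeline at each level. The same classification seed is
#' used at every level, so the zero-noise row reproduces the unperturbed
#' result exactly.
#'
#' @param networks list of per-subject symmetric P x P matrices.
#' @param labels subject labels.
#' @param sd_grid non-negative, non-decreasing noise standard deviations.
#' @param n_repeats CV repeats per noise level.
#' @param seed master seed (noise draws and CV splits).
#' @param ... further arguments passed to [nested_cv_classify()].
#' @return data.frame with columns \code{noise_sd}, \code{acc_mean},
#'   \code{acc_sd}.
#' @export
noise_robustness_experiment <- function(networks, labels, sd_grid,
                                        n_repeats = 10L, seed = 1L, ...) {
  if (any(sd_grid < 0))
    stop_validation("noise standard deviations must be >= 0")
  if (is.unsorted(sd_grid))
    stop_validation("sd_grid must be non-decreasing")
  P <- nrow(networks[[1L]])
  ut <- upper.tri(matrix(0, P, P))
  res <- lapply(seq_along(sd_grid), function(si) {
    sdv <- sd_grid[si]
    noisy <- with_seed(derive_seed(seed, si), lapply(networks, function(W) {
      V <- unclass(W)
      Z <- matrix(0, P, P)
      Z[ut] <- stats::rnorm(sum(ut), sd = sdv)
      V + Z + t(Z)
    }))
    rep <- nested_cv_classify(edge_feature_matrix(noisy), labels,
                              n_repeats = n_repeats, seed = seed, ...)
    c(acc_mean = rep$acc_mean, acc_sd = rep$acc_sd)
  })
  data.frame(noise_sd = sd_grid,
             acc_mean = vapply(res, `[[`, numeric(1), "acc_mean"),
             acc_sd = vapply(res, `[[`, numeric(1), "acc_sd"))
}
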