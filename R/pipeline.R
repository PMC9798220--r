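# End-to-end orchestration: decompose -> construct -> fuse -> classify,
# with per-subject caching of band signals and scheme routing.

# Band signals for one subject under a config; cached as two TSVs at
# full (%.17g) precision so cached and fresh values are bit-identical.
subject_bands <- function(subject, config, cache_dir = NULL) {
  tag <- subject$subject_id
  if (!is.null(cache_dir)) {
    hi_p <- file.path(cache_dir, paste0(tag, "_high.tsv"))
    lo_p <- file.path(cache_dir, paste0(tag, "_low.tsv"))
    if (file.exists(hi_p) && file.exists(lo_p)) {
      return(list(high = read_cached_matrix(hi_p),
                  low = read_cached_matrix(lo_p)))
    }
  }
  X <- normalize_roi_signals(subject$values)
  params <- eemd_params(ensemble_size = config$ensemble_size,
                        noise_amplitude = config$noise_amplitude,
                        max_sift = config$max_sift,
                        sift_sd_threshold = config$sift_sd_threshold,
                        min_support = config$min_support,
                        seed = derive_seed(config$seed, match_id(tag)))
  bands <- decompose_signals(X, method = config$decomposition,
                             params = params,
                             include_residual = config$include_residual)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    write_cached_matrix(bands$high, hi_p)
    write_cached_matrix(bands$low, lo_p)
  }
  bands
}

# Stable integer from a subject id (for per-subject seed derivation).
match_id <- function(id) sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))

write_cached_matrix <- function(M, path) {
  con <- file(path, "w")
  writeLines(apply(M, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t")), con)
  close(con)
}

read_cached_matrix <- function(path) {
  rows <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

# One network (or feature vector, for scheme "concat") for one subject at
# one grid value.
subject_network <- function(signals_high, signals_low, signals_full,
                            scheme, fbn_method, gval, config) {
  build <- function(X, band) {
    if (fbn_method == "pc") {
      threshold_network(pearson_network(X, band = band), gval)
    } else {
      sparse_representation_network(X, lambda = gval, band = band)
    }
  }
  switch(scheme,
    full = build(signals_full, "full"),
    high = build(signals_high, "high"),
    low = build(signals_low, "low"),
    mbnf = snf_fuse(build(signals_high, "high"), build(signals_low, "low"),
                    k = min(config$snf_k, nrow(signals_high) - 1L),
                    tol = config$snf_tol,
                    max_iter = config$snf_max_iter, mode = config$snf_mode),
    concat = concatenate_baseline(build(signals_high, "high"),
                                  build(signals_low, "low")))
}

#' Build per-grid edge-feature matrices for a cohort
#'
#' Runs decomposition (unless \code{scheme = "full"}) and network
#' construction for every subject and hyperparameter candidate, returning
#' the feature matrices [nested_cv_classify()] consumes. For
#' \code{scheme = "mbnf"} each candidate's band networks are fused by SNF
#' before vectorization.
#'
#' @param subjects list of \code{roi_timeseries}.
#' @param config a [run_config()].
#' @param grid hyperparameter candidates; defaults to the config's
#'   sparsity grid (PC) or lambda grid (SR).
#' @param cache_dir optional directory for cached band signals.
#' @param progress print one line per subject processed.
#' @return named list of N x E feature matrices, one per grid value.
#' @export
cohort_features <- function(subjects, config = run_config(), grid = NULL,
                            cache_dir = NULL, progress = FALSE) {
  if (is.null(grid))
    grid <- if (config$fbn_method == "pc") config$sparsity_grid
            else config$lambda_grid
  scheme <- config$scheme
  feats <- NULL
  for (s_i in seq_along(subjects)) {
    subj <- subjects[[s_i]]
    full <- normalize_roi_signals(subj$values)
    if (scheme == "full") {
      hi <- lo <- NULL
    } else {
      bands <- subject_bands(subj, config, cache_dir)
      hi <- bands$high
      lo <- bands$low
    }
    for (g_i in seq_along(grid)) {
      net <- subject_network(hi, lo, full, scheme, config$fbn_method,
                             grid[g_i], config)
      v <- if (scheme == "concat") net else edge_vector(net)
      if (is.null(feats))
        feats <- replicate(length(grid),
                           matrix(NA_real_, length(subjects), length(v)),
                           simplify = FALSE)
      feats[[g_i]][s_i, ] <- v
    }
    if (progress)
      message(sprintf("  subject %d/%d done", s_i, length(subjects)))
  }
  names(feats) <- format(grid, trim = TRUE)
  feats
}

#' Run the full pipeline on a cohort
#'
#' Executes decompose, construct, fuse and classify for one scheme,
#' then derives the companion analyses: the discriminative-edge table
#' (t-test on the whole cohort at the most-chosen hyperparameter; for
#' interpretation, not part of the cross-validated evaluation) and the
#' per-ROI frequency-variability profile of class-mean band networks
#' (skipped for \code{scheme = "full"}, which has a single band).
#'
#' @param subjects list of \code{roi_timeseries} (e.g. from
#'   [generate_cohort()] or [read_cohort()]).
#' @param config a [run_config()].
#' @param grid optional hyperparameter grid override (a single value
#'   skips the inner CV).
#' @param cache_dir optional cache directory for band signals.
#' @param progress print progress lines.
#' @return list of class \code{pipeline_result} with \code{report}
#'   (a \code{cv_report}), \code{edges} (data.frame i, j, t, p),
#'   \code{fv} (data.frame per ROI and class, or NULL), \code{config}.
#' @export
run_pipeline <- function(subjects, config = run_config(), grid = NULL,
                         cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(subjects, "synthetic_cohort")) subjects <- subjects$subjects
  labels <- cohort_labels(subjects)
  if (is.null(grid))
    grid <- if (config$fbn_method == "pc") config$sparsity_grid
            else config$lambda_grid
  feats <- cohort_features(subjects, config, grid = grid,
                           cache_dir = cache_dir, progress = progress)
  report <- nested_cv_classify(feats, labels, grid = grid,
                               n_repeats = config$n_repeats,
                               n_folds = config$n_folds,
                               seed = config$seed, alpha = config$alpha,
                               cost = config$cost)

  # interpretation outputs at the hyperparameter the CV chose most often
  g_best <- most_frequent(report$chosen)
  g_idx <- which.min(abs(grid - g_best))
  sel <- suppressWarnings(
    ttest_select(feats[[g_idx]], labels, alpha = config$alpha))
  P <- nrow(subjects[[1L]]$values)
  eidx <- edge_index(P)
  n_feat <- length(sel$p)
  edges <- if (n_feat == nrow(eidx)) {
    data.frame(i = eidx[, 1L], j = eidx[, 2L], t = sel$t, p = sel$p)
  } else {  # concat scheme: two stacked edge blocks
    data.frame(band = rep(c("high", "low"), each = nrow(eidx)),
               i = rep(eidx[, 1L], 2L), j = rep(eidx[, 2L], 2L),
               t = sel$t, p = sel$p)
  }
  edges <- edges[order(edges$p), ]

  fv <- NULL
  if (config$scheme != "full") {
    fv_rows <- lapply(unique(labels), function(lb) {
      idx <- which(labels == lb)
      mh <- matrix(0, P, P); ml <- matrix(0, P, P)
      for (i in idx) {
        b <- subject_bands(subjects[[i]], config, cache_dir)
        mh <- mh + pearson_network(b$high, band = "high")
        ml <- ml + pearson_network(b$low, band = "low")
      }
      v <- frequency_variability(list(high = mh / length(idx),
                                      low = ml / length(idx)))
      data.frame(roi = seq_len(P), class = lb, fv = as.numeric(v))
    })
    fv <- do.call(rbind, fv_rows)
  }
  structure(list(report = report, edges = edges, fv = fv, config = config),
            class = "pipeline_result")
}

most_frequent <- function(x) {
  tab <- table(as.vector(x))
  as.numeric(names(tab)[which.max(tab)])
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> scheme = %s, fbn = %s\n",
              x$config$scheme, x$config$fbn_method))
  print(x$report)
  cat(sprintf("  %d edges at p < %.3g; top edge (%d, %d), p = %.3g\n",
              sum(x$edges$p < x$config$alpha, na.rm = TRUE),
              x$config$alpha, x$edges$i[1L], x$edges$j[1L], x$edges$p[1L]))
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' @param result a \code{pipeline_result}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  rep <- result$report
  out <- list(
    scheme = result$config$scheme,
    fbn_method = result$config$fbn_method,
    seed = result$config$seed,
    n_repeats = rep$n_repeats, n_folds = rep$n_folds,
    acc_mean = rep$acc_mean, acc_sd = rep$acc_sd,
    sen_mean = rep$sen_mean, sen_sd = rep$sen_sd,
    spe_mean = rep$spe_mean, spe_sd = rep$spe_sd,
    auc_mean = rep$auc_mean, auc_sd = rep$auc_sd,
    chosen_hyperparams = as.vector(t(rep$chosen)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
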