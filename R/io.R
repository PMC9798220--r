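# Plain-text readers and writers: ROI time-series matrices, connectivity
# matrices, cohort directories with manifests, and the run configuration.

detect_delim <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a ROI time-series matrix
#'
#' Reads a delimited text file (tab or comma, auto-detected) with one row
#' per ROI and one column per time point, no header. Ragged rows and
#' non-numeric or missing cells are rejected with their position.
#'
#' @param path file path.
#' @param subject_id,label,TR optional metadata attached to the result.
#' @return object of class \code{roi_timeseries}: list with
#'   \code{values} (P x T matrix), \code{subject_id}, \code{label},
#'   \code{TR}.
#' @export
read_roi_timeseries <- function(path, subject_id = NULL, label = NULL,
                                TR = NA_real_) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_validation("%s is empty", path)
  delim <- detect_delim(lines[[1L]])
  rows <- strsplit(lines, delim, fixed = TRUE)
  T_len <- length(rows[[1L]])
  for (r in seq_along(rows)) {
    if (length(rows[[r]]) != T_len)
      stop_validation("%s line %d has %d fields, expected %d",
                      path, r, length(rows[[r]]), T_len)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_validation("%s: non-numeric or missing value at row %d, column %d",
                    path, bad[1L], bad[2L])
  }
  structure(list(values = vals,
                 subject_id = subject_id %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 label = label, TR = TR),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s: P = %d, T = %d, TR = %s, label = %s\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              format(x$TR), x$label %||% "<none>"))
  invisible(x)
}

#' Write / read a connectivity matrix as TSV
#'
#' Matrices are written tab-separated at \code{%.10g} precision with a
#' header row of ROI indices; values round-trip to within 1e-9.
#' \code{read_matrix()} rejects non-square files and warns if the
#' read-back matrix is asymmetric beyond tolerance (reporting the maximum
#' deviation), then symmetrizes.
#'
#' @param W symmetric matrix.
#' @param path file path.
#' @param kind,band attributes restored on read (the file stores values
#'   only).
#' @return \code{write_matrix()} returns \code{path} invisibly;
#'   \code{read_matrix()} a \code{connectivity_matrix}.
#' @export
write_matrix <- function(W, path) {
  check_symmetric(W, tol = 1e-6, what = "matrix")
  V <- unclass(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(seq_len(ncol(V)), collapse = "\t"), con)
  writeLines(apply(V, 1L, function(row)
    paste(sprintf("%.10g", row), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, kind = "pc", band = "full") {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[-1L]
  rows <- strsplit(body, "\t", fixed = TRUE)
  P <- length(rows)
  if (any(lengths(rows) != P))
    stop_validation("%s is not a square matrix (%d rows, %s columns)",
                    path, P, paste(unique(lengths(rows)), collapse = "/"))
  V <- matrix(as.numeric(unlist(rows)), nrow = P, byrow = TRUE)
  if (anyNA(V)) stop_validation("%s contains non-numeric cells", path)
  dev <- max(abs(V - t(V)))
  if (dev > 1e-9)
    warning(sprintf("matrix read from %s asymmetric (max deviation %.3g)",
                    path, dev))
  V <- (V + t(V)) / 2
  if (kind == "pc") diag(V) <- 1 else diag(V) <- 0
  connectivity_matrix(V, kind = kind, band = band)
}

#' Write a synthetic cohort to a directory
#'
#' Lays out one TSV per subject (rows = ROIs, no header),
#' \code{manifest.tsv} with columns subject_id / label / path,
#' ground-truth matrices \code{truth_\{low,high\}_\{control,patient\}.tsv}
#' and the generator settings in \code{spec.yaml}.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(subject_id = character(0), label = character(0),
                    path = character(0))
  for (s in cohort$subjects) {
    rel <- paste0(s$subject_id, ".tsv")
    con <- file(file.path(dir, rel), "w")
    writeLines(apply(s$values, 1L, function(row)
      paste(sprintf("%.10g", row), collapse = "\t")), con)
    close(con)
    man <- rbind(man, data.frame(subject_id = s$subject_id,
                                 label = s$label, path = rel))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (bn in c("low", "high"))
    for (grp in c("control", "patient"))
      write_matrix(cohort$truth[[bn]][[grp]],
                   file.path(dir, sprintf("truth_%s_%s.tsv", bn, grp)))
  sp <- unclass(cohort$spec)
  sp$effect_edges <- apply(cohort$spec$effect_edges, 1L,
                           function(e) paste(e, collapse = "-"))
  yaml::write_yaml(sp, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Validates that subject ids are unique and all referenced matrices
#' share the same dimensions.
#'
#' @param dir cohort directory containing \code{manifest.tsv}.
#' @param TR sampling interval override; defaults to the value in
#'   \code{spec.yaml} when present.
#' @return list with \code{subjects} (list of \code{roi_timeseries}),
#'   \code{manifest} (data.frame) and \code{TR}.
#' @export
read_cohort <- function(dir, TR = NULL) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path))
    stop_validation("no manifest.tsv under %s", dir)
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (anyDuplicated(man$subject_id))
    stop_validation("duplicate subject ids in manifest")
  if (is.null(TR)) {
    spec_path <- file.path(dir, "spec.yaml")
    TR <- if (file.exists(spec_path))
      yaml::read_yaml(spec_path)$TR else NA_real_
  }
  subjects <- lapply(seq_len(nrow(man)), function(r)
    read_roi_timeseries(file.path(dir, man$path[r]),
                        subject_id = man$subject_id[r],
                        label = man$label[r], TR = TR))
  dims <- vapply(subjects, function(s) dim(s$values), integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop_validation("subjects disagree on matrix dimensions")
  list(subjects = subjects, manifest = man, TR = TR)
}

#' Pipeline run configuration
#'
#' Gathers every tunable of the pipeline with the framework defaults:
#' EEMD ensemble of 100 at noise amplitude 0.2, KNN kernel with k = 11,
#' SNF tolerance 0.01, SVM C = 1, t-test alpha 0.05, 5-fold CV. The PC
#' sparsity grid holds 20 values (5%..95% step 5%, plus 99%) and the SR
#' lambda grid the 19 values 0.1, 0.15, ..., 0.95, 1. Unknown keys are
#' rejected, and configurations round-trip losslessly through YAML.
#'
#' @param ... named overrides of the defaults listed above.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(...) {
  defaults <- list(
    scheme = "mbnf",              # full | low | high | mbnf | concat
    fbn_method = "pc",            # pc | sr
    TR = 3,
    decomposition = "eemd",       # eemd | emd
    ensemble_size = 100L,
    noise_amplitude = 0.2,
    max_sift = 50L,
    sift_sd_threshold = 0.2,
    min_support = 0.5,
    include_residual = FALSE,
    sparsity_grid = c(seq(0.05, 0.95, by = 0.05), 0.99),
    lambda_grid = seq(0.1, 1, by = 0.05),
    snf_k = 11L,
    snf_tol = 0.01,
    snf_max_iter = 100L,
    snf_mode = "normalized",
    n_repeats = 10L,
    n_folds = 5L,
    alpha = 0.05,
    cost = 1,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_validation("unknown config key(s): %s",
                    paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$scheme %in% c("full", "low", "high", "mbnf", "concat"))
    stop_validation("scheme must be one of full/low/high/mbnf/concat")
  if (!cfg$fbn_method %in% c("pc", "sr"))
    stop_validation("fbn_method must be pc or sr")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return \code{read_config()} returns a validated \code{run_config};
#'   unknown keys in the file are rejected.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  run_config(yaml::read_yaml(path))
}
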