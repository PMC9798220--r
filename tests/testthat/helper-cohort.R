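# Shared fixtures built once per test session: a small effect cohort and a
# band-signal cache reused by the slower cohort-level tests.

.fixtures <- new.env(parent = emptyenv())

# The study cohort: P = 20 ROIs, 30 subjects per group, complementary
# group effects (effect size 0.4) split across the two bands, TR = 3 s.
study_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(
      cohort_spec(effect_band = "both", seed = 7))
  .fixtures$cohort
}

# Desk-scale decomposition settings: EEMD ensemble of 30 (frequency
# ordering of the averaged IMFs is stable from roughly M = 20 upward).
study_config <- function(scheme = "mbnf") {
  run_config(scheme = scheme, ensemble_size = 30L, n_repeats = 10L,
             seed = 2L)
}

study_cache <- function() {
  dir <- file.path(tempdir(), "mbnf-band-cache")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir
}

# EEMD IMF sets for the first `n_subjects` of the study cohort (list of
# lists, one imf_set per ROI), built once.
study_imfsets <- function(n_subjects = 20L) {
  key <- paste0("imfsets", n_subjects)
  if (is.null(.fixtures[[key]])) {
    co <- study_cohort()
    params <- eemd_params(ensemble_size = 30L, seed = 99L)
    .fixtures[[key]] <- lapply(co$subjects[seq_len(n_subjects)], function(s) {
      X <- normalize_roi_signals(s$values)
      lapply(seq_len(nrow(X)), function(i) {
        p <- params; p$seed <- p$seed + i
        eemd(X[i, ], p)
      })
    })
  }
  .fixtures[[key]]
}
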