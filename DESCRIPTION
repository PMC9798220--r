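Package: mbnf
Title: Multi-Band Functional Brain Network Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and evaluates multi-band functional brain networks from
    region-of-interest (ROI) BOLD time series. Signals are adaptively split
    into high- and low-frequency bands by ensemble empirical mode
    decomposition (EEMD), per-band connectivity is estimated by Pearson
    correlation or sparse representation (node-wise lasso), and the band
    networks are blended by similarity network fusion (SNF) over
    KNN-sparsified affinity kernels. Subjects are classified with t-test
    edge-feature selection and a linear support vector machine under
    repeated nested cross-validation. Includes a seeded synthetic-cohort
    generator with band-limited latent sources and planted group effects, a
    per-ROI frequency-variability statistic, and a network-noise robustness
    experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
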