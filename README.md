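# mbnf — multi-band functional brain network fusion

`mbnf` builds and evaluates **multi-band functional brain networks**
from region-of-interest (ROI) BOLD time series. It is aimed at
neuroimaging methods researchers who want a fully scripted, seeded,
desk-scale implementation of the multi-band pipeline — decomposition,
per-band network construction, network fusion, and classification —
together with a synthetic-cohort generator that makes every stage
testable without access to clinical fMRI data.

## The method

Given a P × T matrix of ROI signals (rows standardized to
r(x) = (x − μᵢ)/σᵢ):

1. **Band decomposition (EEMD).** Each ROI signal is decomposed into
   intrinsic mode functions by ensemble empirical mode decomposition:
   M noise-perturbed copies are sifted by cubic-spline envelope
   subtraction, and the f-th IMFs are averaged across the ensemble.
   IMF1 (spectral centroid ≈ 0.06–0.16 Hz at TR ≈ 3 s) is the
   high-frequency signal; the summed remaining IMFs are the
   low-frequency signal.
2. **Network construction.** Per band, either Pearson correlation

   $$W_{ij} = \frac{(x_i-\bar x_i)^T (x_j-\bar x_j)}
     {\|x_i-\bar x_i\|\,\|x_j-\bar x_j\|}$$

   with magnitude thresholding (keep the strongest fraction of edges),
   or sparse representation: node-wise lasso
   $\min_w \|x_i - \sum_{j\ne i} w_j x_j\|^2 + \lambda\|w\|_1$,
   symmetrized as (W + Wᵀ)/2.
3. **Similarity network fusion (SNF).** Each band's |W| is reduced to
   a KNN kernel S (k = 11 neighbors per node; non-neighbors zeroed) and
   the two networks cross-diffuse,
   $P_{high} \leftarrow S_{high}\,P_{low}\,S_{high}^T$ (and vice
   versa), with lazy-diffusion normalization, until the Frobenius
   change of both iterates is ≤ 0.01. The fused network is the average
   of the final iterates.
4. **Classification.** Upper-triangle edge weights → per-edge
   two-sample t-tests (p < 0.05, fit on training folds only) → linear
   SVM (C = 1), inside a repeated stratified nested 5-fold CV with the
   construction hyperparameter chosen by inner CV. Reports
   ACC/SEN/SPE/AUC as mean ± sd over repeats.

Per-ROI **frequency variability**,
FVᵢ = 1 − mean over band pairs of corr(FC_f,i, FC_g,i), quantifies how
much each region's connectivity profile changes between bands, and
`noise_robustness_experiment()` measures how classification degrades
when symmetric Gaussian noise is added to the networks.

## Worked example

```r
library(mbnf)

spec <- cohort_spec(n_per_group = 15, P = 12, effect_band = "high",
                    effect_edges = cbind(c(1, 3, 5), c(2, 4, 6)), seed = 42)
co <- generate_cohort(spec)
co
#> <synthetic_cohort> 30 subjects (15/group), P = 12, T = 137, TR = 3s
#>   effect: +0.40 on 3 high-band edge(s), noise sd 0.50, seed 42

cfg <- run_config(scheme = "high", decomposition = "emd",
                  n_repeats = 5L, seed = 1L)
res <- run_pipeline(co, cfg, grid = c(0.3, 0.6, 0.9))
res
#> <pipeline_result> scheme = high, fbn = pc
#> <cv_report> 5 x 5-fold CV
#>   ACC 97.33 +/- 2.79   SEN 94.67 +/- 5.58
#>   SPE 100.00 +/- 0.00   AUC 100.00 +/- 0.00
#>   6 edges at p < 0.05; top edge (3, 4), p = 8.32e-11

head(res$edges, 3)
#>    i j         t            p
#> 22 3 4 10.065982 8.322505e-11
#> 1  1 2  7.728214 2.031777e-08
#> 39 5 6  5.819058 2.981184e-06
```

The cohort planted a +0.4 correlation shift on the high-band edges
(1,2), (3,4), (5,6) in patients; the pipeline classifies held-out
subjects at 97% accuracy and its discriminative-edge table recovers
exactly the three planted edges as the top hits — the t column is the
group-difference statistic per edge, the p column its uncorrected
two-sided p-value.

A shell-oriented front end with the same stages
(`simulate`, `decompose`, `construct`, `fuse`, `fv`, `classify`,
`noise-test`, `run`) ships in `inst/cli/mbnf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mbnf.R", package = "mbnf"))')" \
    simulate --out cohort_dir --seed 1
```

## Vignette

`vignettes/mbnf-methods.Rmd` documents the models, every tunable
parameter with its default and rationale, the numerical choices, what
the synthetic cohorts do and do not emulate, and the known limitations
of fused-network edge features.
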