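---
title: "Multi-band functional brain networks: models, choices, and limits"
author: "mbnf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-band functional brain networks: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbnf)
```

## The problem and the model

Resting-state fMRI yields one BOLD time series per brain region (ROI).
Functional brain networks (FBNs) summarize the pairwise statistical
dependence of these signals, and differences in FBN structure between
patients and controls are used both as classifiers and as candidate
biomarkers. Conventional analyses build one network from the full
band-passed signal; `mbnf` implements a multi-band alternative:

1. **Decompose** each ROI signal adaptively into intrinsic mode functions
   (IMFs) with ensemble empirical mode decomposition (EEMD). The first
   IMF — empirically concentrated around 0.06–0.16 Hz for BOLD-like
   signals sampled at TR ≈ 3 s — forms the *high-frequency* signal; the
   summed remaining IMFs form the *low-frequency* signal.
2. **Construct** a network per band, either by Pearson correlation (PC)
   with magnitude thresholding, or by sparse representation (SR):
   node-wise lasso regression of each ROI signal on all others.
3. **Fuse** the two band networks into one matrix with similarity
   network fusion (SNF): cross-diffusion of each band's network through
   the other band's KNN-sparsified affinity kernel.
4. **Classify** subjects from the fused network's upper-triangle edge
   weights: per-edge two-sample t-tests (p < 0.05) select features on
   the training subjects, and a linear SVM (C = 1) predicts the held-out
   fold, inside a repeated, stratified, nested 5-fold cross-validation.

A per-ROI *frequency variability* statistic,
$FV_i = 1 - \mathrm{mean}_{f<g}\,\mathrm{corr}(FC_{f,i}, FC_{g,i})$,
summarizes how much region *i*'s connectivity profile changes between
bands, and a noise-robustness experiment perturbs the networks with
symmetric Gaussian noise and re-runs the classification.

Two conventions pin FV down. The profile $FC_{f,i}$ is column *i* of
the band-f network with the diagonal entry removed (self-connections
are degenerate), and the mean runs over *unordered* band pairs, so
identical band networks give FV = 0 and sign-flipped ones FV = 2 —
higher means more band-dependent. Note the statistic's direction
depends on *where* a band-specific connection lands: an extra edge to
a region that is already a neighbor in the other band *aligns* the two
profiles and lowers FV, while an edge crossing communities in both
bands decorrelates them and raises it.

## Signal decomposition

EMD sifts a signal by repeatedly subtracting the mean of cubic-spline
envelopes through its local maxima and minima. Choices that the
literature leaves open, and what this package does:

* **Sift stopping.** The Cauchy criterion
  $SD = \sum(h_{prev}-h_{new})^2 / \sum h_{prev}^2 < 0.2$, at most 50
  sifts per IMF. These are the classical settings and both are
  arguments.
* **Envelope boundaries.** Extrema are mirror-extended two deep at each
  end, reflecting about the outermost extremum and clamping to the end
  sample when the record overshoots the envelope there (the symmetrized
  boundary treatment standard in reference EMD implementations). Plain
  reflection about the end sample produces end swings that contaminate
  the deep IMFs. Envelopes use `stats::spline(method = "fmm")`, the
  closest match to the not-a-knot cubics of the canonical MATLAB/Python
  implementations.
* **Decomposition stopping.** Extraction stops when the residual has
  fewer than two interior extrema, or when its range falls below
  1e-10 of the input range. The latter floor matters: once a signal is
  exhausted, floating-point dust in the residual still has "extrema"
  and would otherwise be sifted into phantom IMFs with energies near
  1e-30.
* **EEMD averaging.** Each of the `M` trials decomposes the signal plus
  white noise of standard deviation `0.2 * sd(x)` (`M = 100` and 0.2
  are the canonical defaults; both are parameters). Trials disagree on
  their IMF count, so the f-th output is the mean over all trials, with
  zeros for trials lacking component f. An output component is only
  *emitted* if at least half the trials produced it (`min_support`):
  without this rule, some trial almost always goes one level deeper
  than the rest, leaving a vanishing-energy tail component whose
  spectral centroid is meaningless and violates the expected
  high-to-low frequency ordering of IMFs. Unemitted mass stays in the
  residual, so `x = sum(IMFs) + residual` holds exactly in all cases.
* **Residual handling.** The EMD residual (a monotone trend) is
  excluded from the low band by default; `include_residual = TRUE`
  folds it in. Inputs are assumed detrended/band-passed, as is standard
  for rs-fMRI.
* **Average frequency.** The frequency of a component is its
  periodogram centroid over (0, Nyquist]; a zero-crossing estimator is
  available via `average_frequency(method = "zero_crossing")`.

## Network construction

Signals are standardized row-wise (mean 0, sd 1) before any estimation.
PC networks are thresholded by *magnitude*: the `keep_fraction` of
edges with largest |W| survive (negative correlations can be strong
edges), ties at the cutoff are all kept, and `keep_fraction = 1` is the
identity. SR solves, per node,
$\min_w \|x_i - \textstyle\sum_{j\neq i} w_j x_j\|^2 + \lambda \|w\|_1$
by cyclic coordinate descent on precomputed Gram matrices to a KKT
violation of 1e-6 (at most 10^4 sweeps; non-convergence is reported
with the attained violation). The penalty multiplies the l1 term
directly — no 1/(2T) factor — so `lambda` grids match the convention in
which candidate values run over 0.1, 0.15, …, 0.95, 1 (19 values).
Because each node is solved separately, the coefficient matrix is
asymmetric; it is symmetrized as (W + Wᵀ)/2, since downstream edge
features and fusion require one value per pair.

## Similarity network fusion

Both band networks are reduced to non-negative affinities A = |W| (the
magnitude convention again), and each node's k strongest neighbors
define its KNN kernel (k = 11 by default, the setting used with
116-ROI atlases; ties at rank k are all kept, making the kernel
deterministic). Two modes:

* **normalized** (default): the canonical lazy-diffusion form. KNN
  kernels are oriented so neighborhoods lie along rows and are
  row-normalized; the status matrices are normalized as
  $P \leftarrow P/(2\,\mathrm{rowSums}(P)) + I/2$ at initialization and
  after every update, keeping half of each node's diffusion mass on
  itself. The two matrices update simultaneously
  ($P_{high} \leftarrow S_{high} P_{low} S_{high}^T$ and vice versa,
  each symmetrized), and iteration stops when the Frobenius change of
  *both* falls to `tol = 0.01`, or at `max_iter`. The lazy anchor is
  essential: bare simultaneous cross-updates oscillate between the two
  views and never converge.
* **literal**: the bare update rule with no normalization, provided for
  verifying the algebra on small examples. On realistic scales the raw
  products shrink or explode geometrically (the kernel's spectral
  radius is not 1), so this mode is unsuitable for data analysis.

The fused network is the elementwise mean of the two final iterates,
diagonal zeroed. The concatenation baseline (`concatenate_baseline()`)
simply splices both bands' edge vectors.

## Evaluation protocol

Labels are binary with *patient* as the positive class for
sensitivity/specificity. Edge features are the row-major upper
triangle. The nested CV protocol is leakage-free by construction:
stratified outer 5-folds (repeated, default 10 times, each repeat
reseeded deterministically from the master seed); an inner stratified
5-fold CV on each outer-training set picks the construction
hyperparameter (PC keep-fraction or SR lambda) by mean inner accuracy,
ties toward the smaller value; the t-test mask is fit on outer-training
subjects only. Per repeat, confusion counts pool over the five folds
and AUC comes from the pooled SVM decision scores; means ± sd over
repeats are reported. The t-test is pooled-variance by default (Welch
via `var_equal = FALSE`), uncorrected for multiplicity — it is a
feature filter, not an inference. If no edge passes the threshold the
single smallest-p edge is used, since the SVM needs at least one
input. The SVM is linear with C = 1; with far more edges than subjects
a linear, strongly regularized classifier is the conventional choice.

Repeats default to 10 rather than the hundreds-to-thousands sometimes
used with this protocol; at 10 repeats the Monte-Carlo error of the
mean accuracy is already well below the between-scheme differences the
package is used to measure, and the cost stays desk-scale.

## The synthetic cohort generator

`generate_cohort()` draws two groups of subjects whose ROI signals are
sums of a low-band component (0.015–0.06 Hz), a high-band component
(0.06–0.15 Hz) and white noise. These bands are the conventional
rs-fMRI band-pass range split at the boundary that separates the first
intrinsic mode from the rest at TR = 3 s. Within each band, ROIs in the
same community load a shared latent with weight √within_corr, so the
band-limited correlation is `within_corr` (default 0.6, a typical
within-module resting-state coupling) inside communities and 0 across.
Communities differ between bands (consecutive blocks in the low band,
interleaved in the high band) so each band carries distinct structure.
Latents are white noise shaped by a hard FFT band mask — simple,
exactly band-limited, and controllable.

Group effects are planted by re-weighting, not adding, variance: the
members of each effect component share an extra latent with weight
√effect_size in the effect band, their idiosyncratic weight shrinking
to compensate, so every signal stays unit-variance and the target
correlation on effect edges shifts by exactly `effect_size` in
patients. Effect components must be cliques (disjoint pairs by
default); a clique over m ROIs plants a distributed subnetwork effect
on all its edges. `effect_band = "both"` alternates components between
bands, planting complementary effects. Defaults — 30 subjects per
group, 20 ROIs, 137 time points, TR 3 s, effect size 0.4, noise sd 0.5
— mirror the desk-scale study conditions used throughout the package's
checks, with T = 137 matching the typical number of retained volumes
in the motivating acquisition protocol.

What the generator does **not** emulate: hemodynamic response shapes,
scanner drift, motion or physiological artifacts, non-stationarity,
spatially correlated noise, and realistic inter-subject variability in
community structure. Passing checks on this cohort therefore
demonstrate the pipeline's statistical machinery — calibration,
determinism, leakage-freedom, recovery of planted structure — not
performance on real fMRI.

## Problem sizes used in the package's own checks

The bundled tests and the acceptance script run on: 100 random signals
(T = 137) for reconstruction; a 20-subject slice of the study cohort
for spectral ordering; the full 60-subject study cohort (P = 20, both
bands carrying effects) with an EEMD ensemble of M = 30 for the scheme
comparison and robustness experiments; a null cohort with P = 64
(2016 edges) for selection calibration. M = 30 is used instead of the
M = 100 default because the averaged-IMF frequency ordering is already
stable from roughly M = 20 upward and decomposition cost is linear in
M; both values are exposed as parameters.

## Numerical choices

* Symmetry is validated at 1e-9 and restored exactly by (W + Wᵀ)/2
  where construction can leave 1e-12-scale asymmetry.
* Matrices on disk are TSV at `%.10g` (round-trip error below 1e-9);
  the decomposition cache uses `%.17g` (bit-exact round trip).
* Lasso coordinate descent stops at KKT violation 1e-6; SNF at
  Frobenius change 0.01 on both iterates; both caps are reported when
  hit.
* All randomness (latents, noise, EEMD perturbations, CV splits,
  permutations) derives from explicit seeds; derived sub-seeds stay
  below 2³¹ and the caller's RNG state is restored.
* Degenerate inputs fail loudly and name the offending ROI/edge:
  constant rows, all-zero IMFs, zero-variance connectivity profiles,
  single-class folds.

## A limitation worth knowing about

On this synthetic family, the SNF-fused network is *not* a better
edge-feature representation than the single-band networks, even when
the two bands carry complementary group effects: cross-diffusion
through row-normalized KNN kernels smears an edge-localized correlation
shift across whole neighborhoods and adds subject-specific variance
from the discrete neighbor selection, so per-edge t statistics shrink
several-fold while the simple concatenation of both bands' edges
retains the full complementary signal. Users whose group effects are
expected to be localized to a few connections should prefer
`scheme = "concat"` (or single-band analysis) over `scheme = "mbnf"`;
fusion is most plausible where effects are distributed and the
per-band networks are noisy. The package reports whatever the data
show — the scheme comparison in `scripts/acceptance.R` computes all
five schemes side by side.
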