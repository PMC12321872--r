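---
title: "Dynamic gray-white matter connectivity: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic gray-white matter connectivity: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

This vignette documents the statistical model behind `dynconn`, the defaults
that matter numerically, what the synthetic-cohort generator does and does
not emulate, and the decisions taken where the methodology left genuine
freedom. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The dynamic-variability statistic

For two node signals $x, y$ observed at $T$ timepoints (one sample per TR),
static functional connectivity is the Fisher-z of the whole-scan Pearson
correlation. Dynamic FC slides a window of length $L$ TRs with step $s$ TRs
(`sliding_windows()` yields $\lfloor (T-L)/s \rfloor + 1$ windows; at $s=1$
the consecutive-window overlap is $(L-1)/L$ — 98% for $L = 50$, 95% for $L =
20$). Within each window a taper $w$ downweights edge samples and the
weighted correlation

$$ r_w(x,y) = \frac{\sum_t w_t (x_t-\bar x_w)(y_t-\bar y_w)}
  {\sqrt{\sum_t w_t (x_t-\bar x_w)^2\;\sum_t w_t (y_t-\bar y_w)^2}}, \qquad
  \bar x_w = \sum_t w_t x_t, $$

is Fisher transformed, $z = \tfrac12 \ln\frac{1+r}{1-r}$. The per-edge
summary is the standard deviation of $z$ across windows ("dynamic
variability"). Assumptions worth keeping in mind: the statistic conflates
genuine coupling fluctuation with sampling noise of windowed correlations
(which grows as $1/\sqrt{L}$), so *comparisons* across groups at a fixed
window are meaningful while absolute SD values are not; and heavy window
overlap means the effective number of independent windows is roughly $T/L$,
not the window count.

### Conventions and defaults

* **Taper shapes.** Hamming $0.54 - 0.46\cos(2\pi k/(L-1))$; Gaussian with
  $\sigma = L/6$ TRs by default so that $\pm 3\sigma$ spans the window (no
  standard exists; this is the common "whole window within three sigmas"
  choice); rectangular for the literal unweighted formula. Weights are
  strictly positive and normalized to sum 1; uniform weights reproduce the
  unweighted estimator to $10^{-12}$ (property-tested).
* **z-clipping.** $r$ is clipped to $\pm(1 - 10^{-7})$ before `atanh`, so z
  is always finite (a duplicated series yields the clipped maximum rather
  than infinity).
* **Zero variance.** A constant signal inside a window gives $r = 0$ plus a
  warning, never NaN propagation.
* **SD divisor.** Population convention (divide by the window count $n$),
  with $n-1$ behind `sd_divisor = "n-1"`. With 100+ overlapping windows the
  difference is far below any decision threshold; the population convention
  makes the "identical windows → SD exactly 0" identity exact.
* **Window units.** Window lengths are counted in TRs throughout. Usage
  that quotes windows in seconds should convert with the TR before building
  a `window_spec`.
* **Band-pass.** `bandpass()` is a zero-phase frequency-domain filter:
  Fourier components outside [low, high] (and DC) are zeroed. No IIR
  forward–backward machinery is shipped in the target environment, and the
  ideal FFT filter is what the standard rs-fMRI preprocessing pipelines
  apply at this stage; it passes the in-band/out-of-band variance oracles in
  the test suite exactly.

## 2. White-matter parcellation and its validation

`kmeans_parcellate()` standardizes each voxel series to zero mean and unit
variance (so clustering is driven by signal shape, not amplitude), excludes
zero-variance voxels with a warning, and runs K-means with k-means++ seeding,
keeping the best of `n_init` restarts by within-cluster sum of squares.
Random-partition initialization demonstrably merges/splits clusters at
$k \approx 12$; k-means++ is the same remedy scikit-learn applies by
default. The degenerate $k = n$ case (singleton clusters, zero inertia) is
routed through Lloyd iterations, which tolerate it.

Reproducibility is assessed by splitting the data into `n_subsets` disjoint
subsets — by subject when a list of matrices is supplied, otherwise by
contiguous timepoint blocks — parcellating each subset independently and
averaging the pairwise **matched Dice**: clusters are first matched
one-to-one by maximizing total overlap (Hungarian assignment on the
contingency table), because Dice between unmatched K-means labelings is
meaningless under label permutation. The conventional acceptance bound for a
stable parcellation is mean Dice > 0.85; the bundled synthetic 12-cluster
benchmark reaches 1.0 (computed by `scripts/acceptance.R`).

Where a finer region set than the network-level $k \le 22$ sweep is wanted
(e.g., 128 regions across 12 networks), `hierarchical_parcellate()` refines
each network by a second K-means stage, allocating regions to networks
proportionally to size. How a specific 128-region atlas arises from a
$k \le 22$ sweep is not derivable from the methodology it mimics, so both
the flat and the two-stage readings are exposed rather than guessing one.

## 3. ComBat harmonization

`combat()` implements the parametric empirical-Bayes location/scale model:
features are standardized on a covariate-adjusted OLS fit, per-site means
are shrunk under a normal prior and per-site variances under an
inverse-gamma prior (moment-matched hyperpriors, iterative
conditional-mode solution), and the data are reconstructed with covariate
(e.g. diagnostic group) effects preserved. Two deliberate deviations from
the most common implementation, both documented because they are visible in
tests:

* Site variances are estimated from **covariate-adjusted residuals** with
  the population divisor, consistent with the pooled-variance estimator.
  This removes the df mismatch that otherwise makes repeated application
  drift by a few tenths of a percent per pass.
* When the batch-effect estimates are identical across features (the
  hyperprior variance $\tau^2 \to 0$ or $s^2 \to 0$), the exact
  complete-shrinkage limit is applied instead of dividing by a
  near-zero moment. In that regime an additive site offset is removed to
  machine precision, and a second application is a numerical fixed point.
  On generic noisy data EB shrinkage intentionally leaves a residual
  fraction of the per-feature site difference (that is the point of
  shrinkage), so exact equalization and exact idempotence should only be
  expected in the degenerate construction; the tests are built accordingly.

A single site returns the input unchanged with a warning; sites need at
least 3 subjects; a rank-deficient batch+covariate design is an error.

## 4. Group statistics

Edge-wise differential connections use the equal-variance two-sample t by
default (Welch by flag). The default multiplicity correction is **none**,
mirroring the convention of reporting raw p < 0.05/0.01/0.001 edge counts in
this literature; Bonferroni and FDR are available and recommended. Type-I
calibration at $\alpha = 0.05$ is enforced by a 1000-edge null simulation in
the acceptance suite. Zero-variance edges get $p = 1$ and a flag.

Chord aggregation sums the **absolute group mean difference** of each
surviving edge into its (subnetwork, subnetwork) cell; "connection strength
exhibiting differences" is ambiguous between $t$, $\Delta$ and mean FC, and
$|\Delta|$ is the choice that keeps the matrix nonnegative and conserves
mass (cell totals equal the sum over entries, tested).

The cross-cohort "similarity coefficient" is defined here as the Pearson
correlation of vectorized upper triangles of two group-mean FC matrices.
The quantity circulates in the literature without a definition; this is a
documented interpretation, not an established identity.

One bundled demographic example deserves a note: for the APOE ε4 carrier
table [[31,16],[163,213]] (34.0% vs 56.7%), the uncorrected Pearson
chi-square gives $X^2 = 8.60$, $p = 0.0034$ — clearly significant at 0.05,
but not below the 0.001 sometimes quoted for it. The acceptance suite
asserts the quoted bound as stated and is expected to stay red there; the
package reports the correct value.

## 5. Classification pipeline

* **LASSO** is L1-penalized logistic regression for class labels (the
  "LASSO regression" naming in this literature rarely distinguishes the
  link); a least-squares mode exists and is held to the closed-form
  soft-threshold solution on an orthonormal design in the tests. $\lambda$
  is chosen by 10-fold CV deviance at `lambda.min` (1-SE by flag).
* **SMOTE** interpolates uniformly on segments between a minority point and
  one of its $k = 5$ nearest minority neighbors. It runs **inside training
  folds only** — the only leakage-safe placement.
* **SVM.** No SVM library ships in the target environment, so a compact SMO
  (sequential minimal optimization) solver is implemented in-package, with
  linear, polynomial, RBF and sigmoid kernels. Defaults: $C = 1$, RBF
  $\gamma = 1/(p \cdot \mathrm{Var}(X))$ (the scikit-learn "scale"
  heuristic), features standardized with training-set parameters. At the
  cohort sizes this package targets (tens to hundreds of subjects) the
  pure-R solver is comfortably fast; it is validated on separable data, the
  XOR construction (linear ≤ 0.75, RBF ≥ 0.95) and permutation nulls.
* **Cross-validation** is stratified k-fold (default 10) with a fixed seed.
  All leakage-prone steps — standardization, LASSO, SMOTE — are refit per
  training fold. The no-leakage property is tested by instrumentation:
  with folds held fixed, flipping every label in one validation fold leaves
  that fold's decision scores bit-identical. Aggregate accuracy/
  sensitivity/specificity are reported as mean ± SD over folds (an "SD over
  repeated CV runs" reading exists; fold-wise SD is implemented), and AUC
  comes from the pooled validation scores by the midrank (Mann–Whitney)
  convention. Multiclass problems go through one-vs-rest with
  macro-averaged metrics.

## 6. Graph-theory features

The feature set behind "static/dynamic graph theory" classifiers is not
standardized, so the implemented set is an explicit superset choice:
per-node strength, Barrat weighted clustering, local efficiency; global
characteristic path length (largest component, flagged when disconnected),
global efficiency, and Louvain modularity (seeded, best of 10 restarts).
Graphs are built by proportional thresholding at density 0.15 by default
(no construction rule is canonical; a sweep option exists), keeping the top
fraction of edges by $|z|$ with lexicographic tie-breaking, then dropping
negative-weight survivors — standard practice for FC graph metrics.
Dynamic graph features are the mean and SD of every metric across
per-window graphs (`dyn_mean.*`, `dyn_sd.*`, e.g. modularity and
path-length variability).

## 7. The synthetic cohort: what it emulates, and what a green test means

`generate_cohort()` draws each subject's node signals from a latent-factor
model $x_i(t) = \sum_e a_{ie}(t) f_e(t) + \varepsilon_i(t)$ with iid
standard-normal factors and noise. Couplings are parameterized **on the
correlation scale**: a planted coupling $c$ produces population correlation
exactly $c$ (loadings $\pm\sigma\sqrt{|c|/(1-|c|)}$, sign carried by one
node). Dynamic edges modulate $c(t) = A\sin(2\pi t/P + \varphi)$ (or a
two-state Markov schedule with mean dwell $P/2$), so the planted correlation
swings sign — which is what gives the SD-of-z statistic its signal. The
signed correlation-scale convention matters: an unsigned loading-scale
reading of "amplitude 0.6" halves the z-excursion and is not reliably
detectable at $T \approx 200$, which a 100-replicate experiment in the test
suite would expose immediately.

Defaults and their rationale (chosen once, not tuned):

* $T = 197$ TRs at TR = 3 s — a plausible modern resting-state length; no
  canonical value exists, so it is configurable.
* Modulation period 60 TRs in the examples — several cycles per scan, slow
  relative to the 20-TR window.
* Between-subject amplitude heterogeneity `amp_sd = 0.25` (truncated to
  keep $|c| < 1$). Subject-level variation must dominate the window-sampling
  noise of the SD-of-z estimate for clinical-scale loadings to be
  recoverable from *measured* variability, which the recovery requirement
  (loading 0.4 recovered within ±0.1 at n = 400) presupposes.
* Clinical scales are `loading × (standardized true variability) +
  √(1−loading²) × noise`, mapped affinely onto realistic group-specific
  score distributions (MMSE ≈ 29.0/28.9/25.8 for CN/SMC/CI, CDR-SB
  0.05/0.21/2.68, APOE ε4 prevalence 0.30/0.34/0.57, amyloid positivity
  0.25/0.30/0.40). The class-imbalance preset reproduces a ~8:1 CI:SMC
  ratio.
* Site effects are **feature-level** additive offsets and multiplicative
  scales (`apply_site_effects()`). Correlation features are invariant to
  affine transforms of raw signals, so batch effects injected into the time
  series would be invisible to every downstream stage; planting them where
  ComBat operates is the only reading that exercises harmonization.

Not emulated, deliberately: volumetric image synthesis, physiological
(cardiac/respiratory) noise, head motion, autocorrelated BOLD noise,
hemodynamic response convolution, and spatial correlation among nodes
beyond the planted edges. A green detection or classification test
therefore establishes that the pipeline recovers the planted covariance
structure under white noise — not that it would survive fMRI artifact
structure; conversely, the generator's ground truth makes failures
attributable.

## 8. Known limitations

* The SMO solver has no shrinking/caching heuristics; thousands of samples
  would need a compiled implementation.
* Parametric ComBat only; no nonparametric prior mode.
* No time-resolved state clustering of window matrices (dFC "states"),
  no wavelet/DCC alternatives, no network-based statistic, and no
  minimum-spanning-tree graph construction.
* Dice-based reproducibility depends on the subset split; with few
  timepoints, contiguous-block splits can alias slow trends into cluster
  differences.
* `run_pipeline()` is a desk-scale orchestrator (it holds per-subject FC in
  memory); cohort sizes in the thousands of nodes would need a streaming
  design.
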