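---
title: "Cold-hot nature identification from HPLC fingerprints: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold-hot nature identification from HPLC fingerprints: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chnis)
```

## The problem

Traditional pharmacology assigns every herbal medicine a binary *nature* —
cold or hot — and the working hypothesis behind this package is that herbs
with the same nature share a similar chemical composition. An HPLC
chromatogram at a fixed UV wavelength summarizes that composition as a
vector of detector absorbances over `d` retention-time channels (thousands
of channels for a 90-minute gradient; the reference panel this method
targets has 61 herbs, 30 cold and 31 hot, at 6,524 channels). The task is:
given a query herb's fingerprint and a panel of fingerprints with known
nature, predict whether the query is cold or hot.

The setting is extreme small-`n` / large-`d`: generic classifiers struggle,
and raw Euclidean or correlation similarity between chromatograms is
dominated by nuisance variation (injection amount, shared major
constituents) rather than by the nature-relevant constituents. The package
therefore learns a task-specific distance before doing any classification.

## The learned metric

Fingerprints are columns of `X` (`d x n`). The learned distance is the
Mahalanobis form

$$d_A(x_i, x_j) = \lVert A^\top (x_i - x_j) \rVert_2,$$

with `A` a `d x u` matrix with orthonormal columns, equivalently a positive
semi-definite quadratic form `M = A Aᵀ` of rank at most `u`. `A` is chosen
to minimize `tr(AᵀQA)` where `Q` combines two ingredients:

1. **Semantic (label) scatter.** Every unordered pair of training samples
   is either an equivalence pair (same label, set `S`) or an inequivalence
   pair (different labels, set `D`). The scatter
   $$P = \sum_{(i,j) \in S} (x_i - x_j)(x_i - x_j)^\top
       \;-\; \lambda \sum_{(i,j) \in D} (x_i - x_j)(x_i - x_j)^\top$$
   makes `tr(AᵀPA)` small when same-nature herbs project close together and
   different-nature herbs project far apart. `lambda_` (default 1) weights
   the repulsive term.

2. **Patch-alignment (geometry) term.** Independently of the labels, the
   chromatograms form a manifold whose local geometry should survive the
   projection. For each sample, a *patch* is the sample plus its `k_patch`
   Euclidean nearest neighbors (default 7). Reconstructing the projected
   patch from its own coordinates by ridge regression (penalty `mu`,
   default `1e3`) has a closed-form residual `YᵢᵀLᵢYᵢ` with
   `Lᵢ = H − H Kᵢ (H Kᵢ H + μI)⁻¹ H` (`H` the patch centering matrix, `Kᵢ`
   the patch Gram matrix); summing the patch matrices over their member
   indices yields the global alignment matrix `L` (symmetric PSD, zero row
   sums), and the term `tr(Aᵀ X L Xᵀ A)`.

The combined objective matrix is `Q = P + X L Xᵀ` (unit weighting; an
optional scalar on the alignment term is exposed but defaults to 1).
Minimizing `tr(AᵀQA)` under `AᵀA = I` is solved exactly by the eigenvectors
of `Q` with the `u` algebraically smallest eigenvalues — these are the
directions along which within-class spread plus local-geometry distortion
is smallest relative to between-class spread.

### Numerical choices

* **Span restriction.** With `d ≫ n`, `Q` has a null space of dimension at
  least `d − n` whose eigenvalue is exactly 0; the "u smallest eigenvalues"
  of the full matrix could select such directions, which carry no
  information about the data (every between-sample difference is orthogonal
  to them). `fit_metric()` therefore solves the eigenproblem restricted to
  the span of the centered training fingerprints (rank at most `n − 1`),
  realized by a QR basis; this also keeps the fit `O(n²d + n³)` instead of
  `O(d³)`. `full_space = TRUE` gives the literal full-space decomposition.
* **Projection dimension.** `u` defaults to `min(n − 1, 30)`, capped by the
  span rank. A consequence worth knowing: when `u` equals the span rank,
  `A` is an orthonormal basis of the entire search space and the learned
  distance is *exactly* Euclidean — the metric only deviates from Euclidean
  when `u` is strictly below the rank (for the 61-herb panel, `u = 30` of
  rank 60). This is tested as a regression property.
* **Determinism.** Eigenvector signs are fixed by making each column's
  largest-magnitude entry positive; patch-neighbor and retrieval ties break
  by dataset order (stable sorts). Refits on identical input are
  bit-identical. `Q` is symmetrized before decomposition and matrices with
  relative asymmetry above `1e-6` are rejected.
* **Degenerate inputs.** A single-class training set is rejected; an empty
  `D` (possible with user-supplied constraints) simply drops the repulsive
  term; `μ > 0` guarantees the patch solve is well-posed even with
  duplicated samples.

## From distances to a nature call

For a query `q`, the `r` references with the smallest learned distances are
retrieved (default `r = 7`; `r = 5` is also a reasonable operating point
and both sit in the sweep grid). Each neighbor gets the inverse-distance
weight `Wᵢ = 1/dᵢ` and the *cold probability* is the weighted vote

$$P_q = \frac{\sum_{i \in \text{cold}} W_i}{\sum_{i} W_i},$$

with the call **cold** when `P_q ≥ 0.5` (inclusive at the boundary). A
zero distance would make the weight infinite, so weights are computed as
`1/max(dᵢ, ε)` with `ε = 1e-12 ×` the median non-zero retrieved distance
(absolute floor `1e-300`): an exact-duplicate fingerprint then dominates
`P_q`, which is the intended behavior — an identical chromatogram should
determine the nature.

```{r worked}
# worked weighting example: neighbors (cold, hot, cold) at distances 1, 2, 4
cold_probability(c("cold", "hot", "cold"), c(1, 2, 4))  # (1 + 1/4) / (7/4)
```

## Evaluation protocols

* **Stability (leave-one-out).** Each of the `n` samples is held out in
  turn, the metric is refit on the remaining `n − 1`, and the held-out
  cold probability is computed. The `n` probabilities feed a confusion
  matrix (cold = positive class), per-class recall/precision/F-score, the
  classification accuracy, the retrieval accuracy (mean fraction of
  retrieved neighbors sharing the query's true label), and a ROC/AUC.
* **Extrapolation (repeated stratified splits).** `n_train` samples
  (default 40 of 61, stratified so roughly 20 per class) train the metric;
  the held-out ~21 are scored; AUC/ACC are summarized as mean ± sample
  standard deviation over `n_repeats` (default 10) splits.
* **ROC construction.** Thresholds sweep the distinct cold probabilities
  (with sentinels forcing the (0,0) and (1,1) endpoints); the trapezoid
  area equals the tie-corrected Mann–Whitney statistic, which the test
  suite verifies against a brute-force concordance count.
* **Baselines.** Plain-Euclidean retrieval and Pearson-correlation
  (`1 − r`) retrieval run through the identical ranking/weighting/scoring
  machinery, so differences isolate the metric. The identity
  transformation reproduces the Euclidean baseline exactly — a reduction
  the tests assert. Reimplementations of LMNN/ITML/ELM are out of scope.

Both "accuracy" flavors are always reported side by side: the
classification accuracy of the thresholded calls (the headline number) and
the retrieval-proportion accuracy of the neighbor lists.

## The synthetic generator

Measured fingerprints for the 61-herb panel are not distributed with the
package (only the panel's names and labels ship, see `herb_panel()`), so
`simulate_dataset()` provides a controllable stand-in for every end-to-end
test. It emulates what matters for the method:

* chromatograms are sums of Gaussian elution peaks on a flat baseline,
  non-negative everywhere;
* both classes share `n_shared_peaks` common peaks (shared constituents —
  nuisance structure), each class adds `n_class_peaks` specific peaks whose
  amplitude scales with `separation` (the nature-relevant signal;
  `separation = 0` makes the classes exchangeable);
* per-sample log-normal amplitude noise (`amplitude_cv`), Gaussian
  retention-time jitter of the peak centers, and additive detector noise
  truncated at zero give right-skewed, strictly non-negative traces.

Defaults are 30 cold + 31 hot samples over 6,524 channels with peak width
8 channels and 30 shared / 6 class peaks — panel-shaped data at realistic
peak density. Class-specific peak centers keep at least two peak-widths
away from all other peaks so overlap does not dominate the difficulty. For
reduced-channel runs (tests and the acceptance script use `d = 250–500` to
keep runtimes in seconds) the package narrows peaks to 3 channels so the
same peak counts fit the shorter gradient; this is a scaling choice, not a
fitted quantity. What the generator does **not** emulate: co-elution and
baseline drift, gradient artifacts, multi-wavelength structure, or any
herb-specific chemistry — passing the synthetic suites shows the machinery
is correct and recovers planted signal, not that any particular accuracy
will be achieved on real chromatograms.

## A caution on null-regime leave-one-out scores

On exchangeable data (`separation = 0`) the leave-one-out AUC of the full
scheme sits systematically *below* 0.5 (around 0.25–0.35 across noise
levels), not at chance. Two effects compound: the held-out sample's own
class is under-represented among the references by exactly one sample (the
classic pessimistic bias of leave-one-out k-NN), and the supervised metric,
fit on exchangeable data, overfits chance class structure of the training
samples so that a held-out query tends to project closer to the opposite
class. The plain-Euclidean baseline shows only the first effect (null AUC
≈ 0.42). Permutation-style significance arguments based on this scheme
should therefore calibrate against its empirical null, not against 0.5.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `lambda_` | 1 | weight of the between-class repulsion in `P` |
| `mu` | `1e3` | patch ridge penalty (an alternative reading of the source configuration is `1e-3`; both are in the sweep grid) |
| `k_patch` | 7 | neighbors per patch |
| `u` | `min(n − 1, 30)` | projection dimension |
| `r` | 7 | retrieved references per query |
| `P_T` | 0.5 | cold-probability decision threshold (inclusive) |
| sweep grids | `λ ∈ 10^{−8..8}`, `μ ∈ 10^{−3..5}`, `r ∈ {1,3,5,7,10,12,15,20}` | `parameter_sweep()` defaults |

## Limitations

* The method presumes aligned retention-time axes across samples; no
  warping or peak alignment is performed (upstream preprocessing).
* Wavelength selection is upstream: one fingerprint per sample at a single
  wavelength.
* With `n ≈ 61`, leave-one-out and 10-split summaries carry substantial
  variance; treat single-run AUC differences below ~0.05 as noise.
* The learned projection is linear; strongly nonlinear class structure is
  out of reach by design.
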