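---
title: "Enhancing sparse single-cell chromatin accessibility data"
author: "scEnhance authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing sparse single-cell chromatin accessibility data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell chromatin accessibility assays (scATAC-seq and relatives)
measure, per cell, which genomic peaks are open. Because each cell
contributes at most two copies of each locus and sequencing is shallow,
the peak-by-cell count matrix is near-binary and extremely sparse: most
truly accessible sites are recorded as zero (dropout). Downstream
analyses -- clustering, embedding, regulatory interpretation -- degrade
badly on such data. *Enhancement* replaces the observed matrix with a
denoised estimate in which each cell borrows strength from similar
cells.

## The model

Let $X \in \mathbb{R}^{m \times n}$ be the preprocessed (TF-IDF
weighted) peak-by-cell matrix. The package jointly learns a
non-negative factorization and a cell-to-cell similarity matrix by
minimizing

$$F(W, H, Z) \;=\; \lVert X (Z \circ R) - W H \rVert_F^2
  \;+\; \lambda \lVert Z - H^\top H \rVert_F^2
  \;+\; \gamma_1 \lVert W \rVert_F^2
  \;+\; \gamma_2 \lVert H \rVert_F^2,
\qquad W, H, Z \ge 0,$$

where $W \in \mathbb{R}^{m \times k}$ maps peaks to $k$ latent
programs, $H \in \mathbb{R}^{k \times n}$ embeds cells, and
$Z \in \mathbb{R}^{n \times n}$ holds cell-to-cell weights (columns sum
to 1 at initialization and output). The first term asks the
similarity-smoothed data $X(Z \circ R)$ and the factorization
reconstruction $WH$ to agree; the second ties each similarity entry to
the inner product of the corresponding embedding vectors; the last two
are ridge penalties against overfitting. $R$ is a fixed binary matrix
with i.i.d. Bernoulli entries, Hadamard-applied to $Z$, whose job is to
stop groups of similar cells from collapsing onto *identical* enhanced
profiles, which would erase real heterogeneity. The enhanced matrix is
the product of a source layer with the optimized column-stochastic
similarity matrix, $X Z$.

The reference-anchored variant splits the projection matrix into
$[W_1, W_2]$ with $W_1 \in \mathbb{R}^{m \times k_1}$ tied to a basis
$P$ extracted by conventional NMF from reference profiles (bulk
samples, pseudo-bulk sums of a labeled dataset, or the data's own
cluster pseudo-bulk) through an extra penalty
$\alpha \lVert P - W_1 \rVert_F^2$. Internally the split is realized as
column blocks, which is exactly equivalent to Hadamard masking the two
summands with a column-block indicator and its complement; the package
tests both forms against each other. With $k_1 = 0$ (empty mask) and
$\alpha = 0$ the variant reduces *bitwise* to the core model, and a
test asserts that too.

## Optimization

All three factors are updated by projected gradient descent. Because
$F$ is an exact quadratic along any fixed direction in $W$ or in $Z$,
those two steps use a closed-form exact line search followed by
clipping at zero; if clipping breaks descent the step is halved until
it does not, and a non-positive line minimizer (possible after
projections) causes the update to be skipped for that iteration with a
warning. One deliberate deviation from the usual presentation of the
$W$ step: the ridge term $\gamma_1\lVert W\rVert_F^2$ does depend on
the step size, so its contribution is included in the closed form --
dropping it (as a derivation that treats the ridge as constant would)
makes the step exact only at $\gamma_1 = 0$. The $H$ step has no closed
form ($H$ enters at fourth order through $\lVert Z - H^\top H
\rVert^2$), so it backtracks: start at $\delta_3 = 0.2$ and halve until
the projected step decreases $F$, down to $10^{-10}$, below which the
update is a no-op. The loss trace is therefore non-increasing by
construction, and the test suite sweeps random instances to confirm it.

Initialization matters for a non-convex objective: $Z$ starts from the
column-normalized Jaccard similarity of binarized profiles (computed on
raw counts when available, because TF-IDF zeroes ubiquitously open
peaks and would distort supports), and $(W, H)$ from conventional NMF
(seeded HALS coordinate descent, implemented in-package). The
reference-anchored fit keeps the *full* embedding from the target NMF
and only replaces the $k_1$ leading projection columns with the
reference basis, rescaled to the NMF column scale (factor scale in NMF
is non-identifiable, so this normalization is free): initializing the
anchored embedding rows randomly instead would pollute $Z$ through the
heavily weighted consistency term and can make the reference fit worse
than the core fit. The mask $R$
is drawn once per fit so the objective is fixed during optimization;
resampling it each iteration would change the function being minimized
and void the monotonicity guarantee. Iteration stops when the relative
change of $F$ between consecutive iterations falls below `tol`
(guarded by $\varepsilon = 10^{-12}$; an absolute-change mode is
available), or at `maxIter`.

## Parameters and defaults

* `k` -- latent dimension. Set it to the expected number of cell
  types; too-small `k` merges types (over-smoothing), very large `k`
  admits noise. `estimateK()` offers an eigengap fallback and warns
  that it is only a heuristic.
* `lambda = 1e6` -- similarity-consistency weight; the published
  default, to which results are robust over orders of magnitude.
* `gamma1 = gamma2 = 1` -- ridge weights. No published values exist;
  unit weights are a neutral choice and are config-exposed.
* `maskP = 0.8` -- Bernoulli probability of the mask. The source
  description leaves it open; 0.8 keeps most similarity information
  while still decorrelating enhanced profiles, and it is
  config-exposed.
* `tol = 1e-6`, `maxIter = 100`, `delta3Init = 0.2`, `seed`.
* Reference fits add `k1` (default `min(s, k - 2)` in the CLI, keeping
  at least two free components for target-specific structure) and
  `alpha = 1`.
* TF-IDF: the inverse-document-frequency denominator is computed on
  *binarized* counts by default, which guarantees a non-negative
  transformed matrix as the NMF requires; the literal raw-count
  denominator (which can go negative on multi-counts) is available via
  `idfOnBinarized = FALSE`. On binary input the two coincide. Natural
  logarithms throughout.
* Peak filter: "open in at least 1% of cells" is implemented as
  `count >= ceiling(0.01 * n)` -- an inclusive boundary.
* `enhanceMatrix()` defaults to multiplying the TF-IDF layer (the layer
  the objective was optimized on); `layer = "counts"` gives the literal
  raw-count product.

## What the synthetic generator does and does not emulate

`simulateAccessibility()` plants `nClusters` disjoint marker-peak
blocks: a cell draws its own cluster's markers Bernoulli(0.6) and
everything else Bernoulli(0.05), and the observed counts thin the truth
binomially with a per-cell lognormal capture factor (capped at 1, mean
about 0.7). The defaults -- 5 clusters x 500 cells x 3000 markers,
i.e. 15,000 peaks by 2,500 cells -- mirror the canonical discrete-mode
benchmark design. `corruptDropout()` then zeroes nonzeros independently
at a chosen rate, and `subsampleCells()` implements the
dataset-shrinking and rebalancing robustness designs.

This captures what the enhancement experiments need: discrete
well-separated populations, near-binary signal, depth variation,
dropout. It deliberately does **not** emulate read-level fragment
structure, peak width/GC biases, batch effects, continuous
differentiation trajectories, or correlated dropout -- so a passing
recovery test says the method restores planted discrete structure under
independent dropout, not that it handles trajectory data or batch
confounding.

## Numerical choices and degenerate inputs

* Ties in peak rankings (specific and background peaks, DA scores) are
  broken by peak order, making outputs deterministic.
* Cells with empty support fail Jaccard initialization loudly; all-zero
  cells fail TF-IDF (the term frequency is undefined).
* Constant cell profiles have undefined Pearson correlation; the
  silhouette assigns such pairs distance 1 with a warning.
* Single-class units (cells or peaks whose truth is all-0 or all-1) are
  skipped in auPRC/auROC and reported, never silently averaged.
* The imbalance degree uses natural logs (the `1/log C` normalization
  makes the base irrelevant) and `0 log 0 = 0`; a single observed type
  requires an explicit type inventory because the formula is degenerate
  at `C = 1`.
* Louvain clustering binary-searches the resolution in `[0, 3]` (up to
  50 probes, 15-neighbor graph -- common single-cell practice, both
  config-exposed) and flags the result when the target cluster count is
  unreachable; ties prefer the lower resolution.
* All randomness flows from a single integer seed; small fixed offsets
  separate the NMF initialization, the mask, the reference NMF and the
  anchored-block embedding rows, so fits are bitwise reproducible.

## Problem sizes used by the tests

The packaged checks run at desk scale, chosen so the whole suite is a
few minutes of single-core work: oracle checks (finite differences,
grid-scan line searches, norm-vs-trace) on 6 x 5 instances with k = 2;
monotone-descent sweeps on 24 x 10 random matrices; recovery and
reference-benefit experiments on 5 clusters x 100 cells with 600
markers per cluster (3,000 peaks x 500 cells) at 60% dropout; and the
simulation-design check at the full 15,000 x 2,500 benchmark size. At
the recovery scale the fitted model restores Louvain clustering of the
corrupted data to a perfect match with the planted labels and raises
mean cell-wise auPRC over the corrupted baseline; the acceptance tests
assert exactly those statements rather than any number quoted from
elsewhere.

## Known limitations

* The full similarity matrix is dense $n \times n$: fits beyond a few
  thousand cells need more memory and time than this implementation
  targets (no mini-batching, no GPU).
* `k` must be supplied or taken from labels; the eigengap fallback is
  rough.
* Depth- and batch-correcting extensions of the objective are out of
  scope, as are read-level simulation and peak calling.
* The optimization is non-convex: different seeds can reach different
  (equally legitimate) local minima; all reported experiments fix
  seeds.

## A worked example

```{r example, eval = FALSE}
library(scEnhance)

sim <- simulateAccessibility(seed = 1)           # 15,000 x 2,500
cor <- corruptDropout(sim, rate = 0.6, seed = 2) # extra dropout
res <- scEnhance(cor, k = 5, seed = 3)           # filter + TF-IDF + fit

rep <- evaluateEnhancement(
    res$x, SummarizedExperiment::colData(sim)$cell_type,
    truth = SummarizedExperiment::assay(sim, "truth"),
    assay = "enhanced", seed = 4)
rep$ari; rep$meanCellwiseAuprc

mono <- specificPeaks(res$fit,
                      SummarizedExperiment::colData(sim)$cell_type,
                      "cluster_1", topN = 100)
exportPeaksBED(mono, "cluster1_specific.bed")
```
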