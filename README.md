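# scEnhance

Enhancement (denoising / imputation) of sparse single-cell chromatin
accessibility data. scATAC-seq peak-by-cell matrices are near-binary
and dominated by dropout: most truly open sites are recorded as zero,
which blurs cell populations and cripples downstream clustering and
regulatory interpretation. **scEnhance** reconstructs the missing
signal by letting each cell borrow strength from the cells it
resembles, while *learning* who resembles whom as part of the model.

## The model

For a TF-IDF-weighted peak-by-cell matrix $X \in \mathbb{R}^{m\times n}$,
the package minimizes, over non-negative factors,

$$F(W,H,Z) = \lVert X(Z\circ R) - WH\rVert_F^2
 + \lambda\lVert Z - H^\top H\rVert_F^2
 + \gamma_1\lVert W\rVert_F^2 + \gamma_2\lVert H\rVert_F^2,$$

where $W$ (peaks × k) holds latent accessibility programs, $H$
(k × cells) embeds cells, $Z$ (cells × cells) is a cell-to-cell
similarity matrix, and $R$ is a fixed random binary mask that keeps
similar cells from collapsing onto identical profiles. $W$ and $Z$ are
updated with closed-form exact line searches (projected to the
non-negative orthant), $H$ with a backtracked projected gradient step,
so the loss is non-increasing by construction. The enhanced matrix is
$XZ$ with the optimized column-stochastic $Z$.

A reference-anchored variant ties $k_1$ columns of $W$ to a basis
extracted by NMF from bulk or pseudo-bulk profiles through an extra
penalty $\alpha\lVert P - W_1\rVert_F^2$, transferring structure from
richer data onto the sparse target.

The package also ships TF-IDF preprocessing with the standard 1%-of-cells
peak filter, peak-level interpretation (cell type-specific and
background peak sets, exported as BED), an evaluation suite
(binary-searched Louvain clustering, ARI/AMI/FMI, Pearson-distance
silhouette, cell-/peak-wise auPRC/auROC, imbalance degree), and a
discrete-cluster synthetic data generator with dropout and subsampling
corruptions so everything is testable offline.

## A worked example

```r
library(scEnhance)

sim <- simulateAccessibility(nClusters = 5, cellsPerCluster = 100,
                             markerPeaksPerCluster = 600, seed = 11)
cor <- corruptDropout(sim, rate = 0.6, seed = 12)   # 60% extra dropout
res <- scEnhance(cor, k = 5, seed = 13)
res$fit
#> EnhanceFit: 3000 peaks x 500 cells, k = 5
#>   iterations: 100 (not converged)
#>   final loss: 1.143072

truth <- SummarizedExperiment::assay(sim, "truth")[rownames(res$x), ]
rep <- evaluateEnhancement(res$x,
    SummarizedExperiment::colData(sim)$cell_type,
    truth = as.matrix(truth), assay = "enhanced", seed = 14)
rep$ari
#> [1] 1
rep$meanCellwiseAuprc
#> [1] 0.5295498
signalRecovery(as.matrix(SummarizedExperiment::assay(res$x, "counts")),
               as.matrix(truth), "cellwise")$meanAuprc
#> [1] 0.4000174
```

Clustering the enhanced data recovers the five planted populations
exactly (ARI = 1), and the mean per-cell precision-recall AUC against
the uncorrupted truth rises from 0.40 (corrupted input) to 0.53
(enhanced) — the dropout zeros have been filled preferentially at truly
accessible sites. `specificPeaks()` / `backgroundPeaks()` then turn the
fitted factors into peak lists for enrichment tools, and
`fitEnhanceRef()` repeats the fit anchored to a pseudo-bulk reference.

A command-line wrapper with `simulate`, `enhance`, `enhance-ref`,
`build-reference`, `specific-peaks` and `evaluate` subcommands is
installed at `system.file("scripts", "scenhance.R", package = "scEnhance")`.

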