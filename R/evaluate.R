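# Evaluation suite: PCA + Louvain clustering with a binary-searched
# resolution, label-agreement metrics, Pearson-distance silhouette,
# per-cell / per-peak signal-recovery AUCs, and the imbalance degree of
# a cell-type size distribution.

#' Principal-component representation of cells
#'
#' Centered (unscaled) PCA of the cells of a peak-by-cell matrix,
#' reduced to `nComponents` dimensions (default 50, the conventional
#' choice for single-cell data).
#'
#' @param x peak-by-cell matrix or `SingleCellExperiment`.
#' @param nComponents dimensions to keep; clamped (with a warning) to
#'   what the data supports.
#' @param assay assay for `SingleCellExperiment` input (defaults to the
#'   most processed available layer).
#' @return cells x components score matrix.
#' @export
pcaReduce <- function(x, nComponents = 50L, assay = NULL) {
    m <- .denseMatrix(x, assay)
    nc <- as.integer(nComponents)
    lim <- min(dim(m)) - 1L
    if (nc > lim) {
        warning("'nComponents' clamped to ", lim, call. = FALSE)
        nc <- lim
    }
    p <- stats::prcomp(t(m), center = TRUE, scale. = FALSE, rank. = nc)
    scores <- p$x
    rownames(scores) <- colnames(m)
    scores
}

# Undirected k-nearest-neighbor graph on Euclidean distances.
.knnGraph <- function(emb, nNeighbors = 15L) {
    n <- nrow(emb)
    nNeighbors <- min(as.integer(nNeighbors), n - 1L)
    d <- as.matrix(stats::dist(emb))
    edges <- lapply(seq_len(n), function(i) {
        nb <- order(d[i, ])[seq_len(nNeighbors + 1L)]
        nb <- setdiff(nb, i)[seq_len(nNeighbors)]
        cbind(i, nb)
    })
    el <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::simplify(g)
}

#' Louvain clustering with a binary-searched resolution
#'
#' Louvain community detection on a nearest-neighbor graph of an
#' embedding, with the resolution parameter binary-searched so the
#' number of communities matches a target (the known number of cell
#' types). If the target is not hit within the probe budget, the closest
#' labeling is returned (ties broken toward the lower resolution) with a
#' mismatch flag.
#'
#' @param embedding cells x dimensions matrix (e.g. from
#'   [pcaReduce()]).
#' @param targetK desired number of clusters (>= 2).
#' @param nNeighbors neighbors in the graph (default 15).
#' @param resolutionBounds search interval (default `c(0, 3)`).
#' @param maxProbes probe budget (default 50).
#' @param seed integer seed (community detection is randomized).
#' @return integer vector of cluster labels with attributes
#'   `resolution`, `nClusters` and `mismatch`.
#' @export
louvainClusters <- function(embedding, targetK, nNeighbors = 15L,
                            resolutionBounds = c(0, 3), maxProbes = 50L,
                            seed = 1L) {
    if (targetK < 2L) stop("'targetK' must be >= 2")
    seed <- .checkSeed(seed)
    g <- .knnGraph(embedding, nNeighbors)
    probe <- function(res) {
        set.seed(seed)
        as.integer(igraph::membership(
            igraph::cluster_louvain(g, resolution = res)))
    }
    lo <- resolutionBounds[1L]; hi <- resolutionBounds[2L]
    best <- NULL; bestGap <- Inf; bestRes <- Inf
    for (i in seq_len(maxProbes)) {
        mid <- (lo + hi) / 2
        lab <- probe(mid)
        kFound <- length(unique(lab))
        gap <- abs(kFound - targetK)
        if (gap < bestGap || (gap == bestGap && mid < bestRes)) {
            best <- lab; bestGap <- gap; bestRes <- mid
        }
        if (kFound == targetK) break
        if (kFound < targetK) lo <- mid else hi <- mid
    }
    attr(best, "resolution") <- bestRes
    attr(best, "nClusters") <- length(unique(best))
    attr(best, "mismatch") <- bestGap > 0
    if (bestGap > 0)
        warning("could not reach exactly ", targetK, " clusters (closest: ",
                attr(best, "nClusters"), ")", call. = FALSE)
    best
}

# Contingency table as a plain integer matrix.
.contingency <- function(a, b) {
    table(factor(a, levels = unique(a)), factor(b, levels = unique(b)))
}

#' Clustering agreement metrics
#'
#' Adjusted Rand index (chance-corrected pair agreement), adjusted
#' mutual information (chance-corrected information overlap, arithmetic
#' normalizer) and Fowlkes-Mallows index (geometric mean of pairwise
#' precision and recall) between a predicted and a true labeling. All
#' three are invariant to label renaming.
#'
#' @param pred,truth label vectors of equal length (>= 2 cells).
#' @return list with elements `ari`, `ami`, `fmi`.
#' @examples
#' clusteringMetrics(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
clusteringMetrics <- function(pred, truth) {
    if (length(pred) != length(truth))
        stop("'pred' and 'truth' must have equal length")
    if (length(pred) < 2L) stop("need at least 2 cells")
    list(ari = mclust::adjustedRandIndex(pred, truth),
         ami = .ami(pred, truth),
         fmi = .fmi(pred, truth))
}

.ami <- function(a, b) {
    tab <- as.matrix(.contingency(a, b))
    N <- sum(tab)
    ai <- rowSums(tab); bj <- colSums(tab)
    nz <- tab > 0
    mi <- sum((tab[nz] / N) *
              log(N * tab[nz] / (ai[row(tab)[nz]] * bj[col(tab)[nz]])))
    hU <- -sum((ai / N) * log(ai / N))
    hV <- -sum((bj / N) * log(bj / N))
    # expected MI under the permutation (hypergeometric) model
    emi <- 0
    for (i in seq_along(ai)) {
        for (j in seq_along(bj)) {
            lower <- max(ai[i] + bj[j] - N, 1L)
            upper <- min(ai[i], bj[j])
            if (upper < lower) next
            for (nij in lower:upper) {
                p <- exp(lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
                         lgamma(N - ai[i] + 1) + lgamma(N - bj[j] + 1) -
                         lgamma(N + 1) - lgamma(nij + 1) -
                         lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
                         lgamma(N - ai[i] - bj[j] + nij + 1))
                emi <- emi + p * (nij / N) * log(N * nij / (ai[i] * bj[j]))
            }
        }
    }
    denom <- (hU + hV) / 2 - emi
    if (abs(denom) < 1e-15) return(1)
    as.numeric((mi - emi) / denom)
}

.fmi <- function(a, b) {
    tab <- as.matrix(.contingency(a, b))
    tp <- sum(choose(tab, 2))
    pa <- sum(choose(rowSums(tab), 2))
    pb <- sum(choose(colSums(tab), 2))
    if (pa == 0 || pb == 0) return(0)
    tp / sqrt(pa * pb)
}

#' Silhouette score on a Pearson-correlation distance
#'
#' Mean silhouette width of cells against their annotated cell types,
#' computed on the distance `d(i, j) = 1 - Pearson(x_i, x_j)` between
#' cell profiles. Used with the true labels (rather than cluster
#' labels), it measures how well the enhanced data separates the known
#' types. Pairs with an undefined correlation (constant profile) are
#' assigned distance 1 with a warning.
#'
#' @param x peak-by-cell matrix or `SingleCellExperiment`.
#' @param labels cell-type labels, >= 2 distinct values.
#' @param assay assay for `SingleCellExperiment` input.
#' @return mean silhouette width (scalar in `[-1, 1]`).
#' @export
silhouettePearson <- function(x, labels, assay = NULL) {
    m <- .denseMatrix(x, assay)
    labels <- as.character(labels)
    if (length(unique(labels)) < 2L)
        stop("need at least 2 distinct labels")
    cc <- suppressWarnings(stats::cor(m))
    if (anyNA(cc)) {
        warning("constant cell profile(s): undefined correlations set to ",
                "distance 1", call. = FALSE)
        cc[is.na(cc)] <- 0
    }
    d <- 1 - cc
    diag(d) <- 0
    sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
    mean(sil[, "sil_width"])
}

# Area under the ROC curve via the Mann-Whitney rank statistic
# (midranks handle ties exactly).
.auroc <- function(scores, truth) {
    np <- sum(truth == 1); nn <- sum(truth == 0)
    r <- rank(scores)
    (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

# Area under the precision-recall curve by step-wise summation over
# distinct score thresholds (average-precision convention).
.auprc <- function(scores, truth) {
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- truth[ord]
    np <- sum(y == 1)
    grp <- cumsum(!duplicated(s))          # tie groups share a threshold
    tp <- cumsum(y)
    fp <- cumsum(1 - y)
    last <- !duplicated(grp, fromLast = TRUE)
    tp <- tp[last]; fp <- fp[last]
    prec <- tp / (tp + fp)
    rec <- tp / np
    sum(diff(c(0, rec)) * prec)
}

#' Signal-recovery AUCs against a binary ground truth
#'
#' Treats enhanced values as scores for the binary true accessibility
#' and computes, per cell (`axis = "cellwise"`) or per peak
#' (`"peakwise"`), the area under the precision-recall curve and under
#' the ROC curve. Units whose truth is single-class carry no ranking
#' information; they are skipped and counted.
#'
#' @param enhanced peak-by-cell matrix of scores (matrix or
#'   `SingleCellExperiment` assay `"enhanced"`).
#' @param truth binary matrix of the same shape (entries coerced at
#'   `> 0`).
#' @param axis `"cellwise"` (default) or `"peakwise"`.
#' @return list with per-unit vectors `auprc`, `auroc` (NA for skipped
#'   units), their means over evaluated units `meanAuprc`, `meanAuroc`,
#'   and `nSkipped`.
#' @export
signalRecovery <- function(enhanced, truth,
                           axis = c("cellwise", "peakwise")) {
    axis <- match.arg(axis)
    E <- .denseMatrix(enhanced, if (is(enhanced, "SummarizedExperiment"))
        "enhanced" else NULL)
    Tr <- (.denseMatrix(truth, if (is(truth, "SummarizedExperiment"))
        "truth" else NULL) > 0) * 1
    if (!all(dim(E) == dim(Tr)))
        stop("'enhanced' and 'truth' must have the same shape")
    if (axis == "peakwise") { E <- t(E); Tr <- t(Tr) }
    nUnit <- ncol(E)
    auprc <- auroc <- rep(NA_real_, nUnit)
    for (j in seq_len(nUnit)) {
        y <- Tr[, j]
        if (all(y == 1) || all(y == 0)) next
        auprc[j] <- .auprc(E[, j], y)
        auroc[j] <- .auroc(E[, j], y)
    }
    ok <- !is.na(auprc)
    if (!any(ok))
        stop("every unit has single-class truth; AUCs undefined")
    list(auprc = auprc, auroc = auroc,
         meanAuprc = mean(auprc[ok]), meanAuroc = mean(auroc[ok]),
         nSkipped = sum(!ok))
}

#' Imbalance degree of a cell-type size distribution
#'
#' One minus the normalized entropy of the type proportions:
#' `I = 1 + (1 / log C) * sum_c (n_c / N) log(n_c / N)` with the
#' convention `0 log 0 = 0`. `I = 0` when all types have equal counts
#' and `I = 1` when a single type holds every cell. `C` is the number of
#' types in `typeInventory` when given (zero-count types allowed),
#' otherwise the number of observed types.
#'
#' @param labels cell-type labels.
#' @param typeInventory optional character vector declaring the full
#'   type inventory; required when only one type is observed.
#' @return scalar in `[0, 1]`.
#' @examples
#' imbalanceDegree(rep(letters[1:4], each = 25))          # 0
#' imbalanceDegree(rep("a", 100), typeInventory = c("a", "b"))  # 1
#' @export
imbalanceDegree <- function(labels, typeInventory = NULL) {
    labels <- as.character(labels)
    if (!is.null(typeInventory)) {
        counts <- vapply(typeInventory, function(t) sum(labels == t),
                         numeric(1))
        if (sum(counts) != length(labels))
            stop("'typeInventory' does not cover all observed labels")
    } else {
        counts <- as.numeric(table(labels))
    }
    C <- length(counts)
    if (C < 2L)
        stop("only one cell type: pass 'typeInventory' declaring the ",
             "full inventory (the formula is degenerate at C = 1)")
    N <- sum(counts)
    p <- counts[counts > 0] / N
    1 + sum(p * log(p)) / log(C)
}

#' Full evaluation report for an enhanced dataset
#'
#' Runs the standard evaluation pipeline: PCA to `nComponents`
#' dimensions, Louvain clustering binary-searched to the number of true
#' types, agreement metrics (ARI/AMI/FMI), the Pearson-distance
#' silhouette on the evaluated layer, and (when a binary ground truth is
#' available) mean cell-wise and peak-wise signal-recovery AUCs.
#'
#' @param x matrix or `SingleCellExperiment` holding the layer to
#'   evaluate.
#' @param trueLabels cell-type labels.
#' @param truth optional binary ground-truth matrix.
#' @param assay assay to evaluate for `SingleCellExperiment` input.
#' @param nComponents,nNeighbors,seed pipeline settings.
#' @return a list (class `"MetricReport"`) with fields `ari`, `ami`,
#'   `fmi`, `silhouette`, optional `meanCellwiseAuprc`,
#'   `meanCellwiseAuroc`, `meanPeakwiseAuprc`, `meanPeakwiseAuroc` and
#'   skip counts, `imbalance`, and provenance (`nClusters`, `seed`).
#' @export
evaluateEnhancement <- function(x, trueLabels, truth = NULL, assay = NULL,
                                nComponents = 50L, nNeighbors = 15L,
                                seed = 1L) {
    m <- .denseMatrix(x, assay)
    trueLabels <- as.character(trueLabels)
    emb <- pcaReduce(m, nComponents)
    k <- length(unique(trueLabels))
    cl <- louvainClusters(emb, targetK = k, nNeighbors = nNeighbors,
                          seed = seed)
    agr <- clusteringMetrics(cl, trueLabels)
    rep <- list(ari = agr$ari, ami = agr$ami, fmi = agr$fmi,
                silhouette = silhouettePearson(m, trueLabels),
                imbalance = if (k >= 2) imbalanceDegree(trueLabels) else NA,
                nClusters = attr(cl, "nClusters"),
                clusterMismatch = attr(cl, "mismatch"),
                seed = seed)
    if (!is.null(truth)) {
        cw <- signalRecovery(m, truth, "cellwise")
        pw <- signalRecovery(m, truth, "peakwise")
        rep$meanCellwiseAuprc <- cw$meanAuprc
        rep$meanCellwiseAuroc <- cw$meanAuroc
        rep$cellsSkipped <- cw$nSkipped
        rep$meanPeakwiseAuprc <- pw$meanAuprc
        rep$meanPeakwiseAuroc <- pw$meanAuroc
        rep$peaksSkipped <- pw$nSkipped
    }
    class(rep) <- c("MetricReport", "list")
    rep
}
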