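# Discrete-cluster synthetic scCAS data. The generator reproduces the
# statistical structure the enhancement experiments need -- disjoint
# cluster-specific accessible peak programs, near-binary counts, per-cell
# depth variation, and tunable dropout -- not any particular read-level
# simulator.

#' Simulate discrete-cluster single-cell accessibility data
#'
#' Generates `nClusters` cell clusters, each with its own disjoint block
#' of marker peaks. Ground-truth accessibility is Bernoulli:
#' `markerOpenProb` on a cluster's own markers, `backgroundOpenProb`
#' elsewhere (and on the optional shared housekeeping block,
#' `sharedOpenProb` for every cell). The observed counts are the truth
#' thinned binomially by a per-cell lognormal depth factor (capped at
#' 1), emulating shallow sequencing. Deterministic given `seed`.
#'
#' The defaults produce the canonical benchmark design: 5 clusters x 500
#' cells with 3000 markers each, i.e. 2500 cells x 15,000 peaks.
#'
#' @param nClusters number of clusters (default 5).
#' @param cellsPerCluster cells per cluster (default 500).
#' @param markerPeaksPerCluster marker peaks per cluster (default 3000);
#'   marker blocks are pairwise disjoint.
#' @param sharedPeaks extra peaks open for all clusters (default 0).
#' @param markerOpenProb,backgroundOpenProb Bernoulli open probabilities
#'   (defaults 0.6 / 0.05); the marker probability must exceed the
#'   background.
#' @param sharedOpenProb open probability of the shared block (default
#'   `markerOpenProb`).
#' @param depthMeanlog,depthSdlog lognormal parameters of the per-cell
#'   depth factor (defaults -0.35 / 0.35, mean capture around 0.7).
#' @param nPeaks optional total peak count; must accommodate the
#'   disjoint marker blocks plus shared peaks.
#' @param seed integer random seed.
#' @return a `SingleCellExperiment` with sparse assays `"counts"`
#'   (observed) and `"truth"` (ground-truth binary accessibility),
#'   `colData$cell_type`, synthetic peak coordinates as `rowRanges`, and
#'   the generator settings in `metadata()$simSpec`.
#' @examples
#' sim <- simulateAccessibility(nClusters = 3, cellsPerCluster = 20,
#'                              markerPeaksPerCluster = 50, seed = 1)
#' sim
#' @export
simulateAccessibility <- function(nClusters = 5L, cellsPerCluster = 500L,
                                  markerPeaksPerCluster = 3000L,
                                  sharedPeaks = 0L,
                                  markerOpenProb = 0.6,
                                  backgroundOpenProb = 0.05,
                                  sharedOpenProb = markerOpenProb,
                                  depthMeanlog = -0.35, depthSdlog = 0.35,
                                  nPeaks = NULL, seed = 1L) {
    nClusters <- as.integer(nClusters)
    cellsPerCluster <- as.integer(cellsPerCluster)
    markerPeaksPerCluster <- as.integer(markerPeaksPerCluster)
    if (markerOpenProb <= backgroundOpenProb)
        stop("'markerOpenProb' must exceed 'backgroundOpenProb'")
    needed <- nClusters * markerPeaksPerCluster + as.integer(sharedPeaks)
    if (is.null(nPeaks)) nPeaks <- needed
    if (nPeaks < needed)
        stop("'nPeaks' (", nPeaks, ") cannot hold ", nClusters,
             " disjoint marker blocks of ", markerPeaksPerCluster,
             " peaks plus ", sharedPeaks, " shared peaks")
    m <- as.integer(nPeaks)
    n <- nClusters * cellsPerCluster
    seed <- .checkSeed(seed)
    set.seed(seed)

    sharedIdx <- if (sharedPeaks > 0)
        seq.int(nClusters * markerPeaksPerCluster + 1L, needed) else integer()
    depth <- pmin(1, stats::rlnorm(n, depthMeanlog, depthSdlog))

    truthBlocks <- vector("list", nClusters)
    obsBlocks <- vector("list", nClusters)
    for (c in seq_len(nClusters)) {
        probs <- rep(backgroundOpenProb, m)
        mk <- seq.int((c - 1L) * markerPeaksPerCluster + 1L,
                      c * markerPeaksPerCluster)
        probs[mk] <- markerOpenProb
        if (length(sharedIdx)) probs[sharedIdx] <- sharedOpenProb
        tr <- matrix(stats::rbinom(m * cellsPerCluster, 1L, probs),
                     m, cellsPerCluster)
        cellIdx <- seq.int((c - 1L) * cellsPerCluster + 1L,
                           c * cellsPerCluster)
        ob <- matrix(stats::rbinom(m * cellsPerCluster, tr,
                                   rep(depth[cellIdx], each = m)),
                     m, cellsPerCluster)
        truthBlocks[[c]] <- as(Matrix::Matrix(tr, sparse = TRUE),
                               "CsparseMatrix")
        obsBlocks[[c]] <- as(Matrix::Matrix(ob, sparse = TRUE),
                             "CsparseMatrix")
    }
    truth <- do.call(cbind, truthBlocks)
    obs <- do.call(cbind, obsBlocks)

    peaks <- parsePeakIntervals(
        data.frame(chrom = "chrS", start = (seq_len(m) - 1L) * 1000L,
                   end = (seq_len(m) - 1L) * 1000L + 500L))
    barcodes <- sprintf("cell_%05d", seq_len(n))
    types <- rep(paste0("cluster_", seq_len(nClusters)),
                 each = cellsPerCluster)
    dimnames(truth) <- dimnames(obs) <- list(names(peaks), barcodes)

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = obs, truth = truth),
        rowRanges = peaks,
        colData = S4Vectors::DataFrame(cell_type = types,
                                       depth_factor = depth,
                                       row.names = barcodes))
    S4Vectors::metadata(sce)$simSpec <- list(
        nClusters = nClusters, cellsPerCluster = cellsPerCluster,
        markerPeaksPerCluster = markerPeaksPerCluster,
        sharedPeaks = as.integer(sharedPeaks),
        markerOpenProb = markerOpenProb,
        backgroundOpenProb = backgroundOpenProb,
        sharedOpenProb = sharedOpenProb,
        depthMeanlog = depthMeanlog, depthSdlog = depthSdlog,
        nPeaks = m, seed = seed)
    .setLayer(sce, "raw")
}

#' Random dropout corruption
#'
#' Zeroes each nonzero entry independently with probability `rate`,
#' emulating additional dropout; zeros are untouched, so corruption only
#' removes signal.
#'
#' @param x `SingleCellExperiment` (assay `"counts"` is corrupted,
#'   other assays untouched) or matrix.
#' @param rate dropout probability in `[0, 1)`.
#' @param seed integer random seed.
#' @return same container with corrupted counts.
#' @export
corruptDropout <- function(x, rate, seed = 1L) {
    if (rate < 0 || rate >= 1)
        stop("'rate' must lie in [0, 1)")
    seed <- .checkSeed(seed)
    dropFun <- function(m) {
        set.seed(seed)
        if (is(m, "sparseMatrix")) {
            m <- as(m, "CsparseMatrix")
            keep <- stats::rbinom(length(m@x), 1L, 1 - rate)
            m@x <- m@x * keep
            Matrix::drop0(m)
        } else {
            nz <- which(m != 0)
            keep <- stats::rbinom(length(nz), 1L, 1 - rate)
            m[nz[keep == 0L]] <- 0
            m
        }
    }
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "counts") <-
            dropFun(SummarizedExperiment::assay(x, "counts"))
        x
    } else {
        dropFun(x)
    }
}

#' Subsample cells by size or toward a target imbalance
#'
#' `mode = "size"` keeps a uniform random subset of cells (a fraction
#' when `level <= 1`, an absolute count otherwise). `mode = "imbalance"`
#' subsamples the larger cell types toward a target imbalance degree
#' (see [imbalanceDegree()]): per-type target counts are interpolated
#' between the observed counts and the size of the smallest type, with
#' the interpolation weight binary-searched so the achieved imbalance
#' matches `level` as closely as subsampling allows.
#'
#' @param x `SingleCellExperiment` or matrix.
#' @param labels cell labels (taken from `colData(x)$cell_type` when
#'   absent).
#' @param mode `"size"` or `"imbalance"`.
#' @param level retained fraction/count, or target imbalance degree.
#' @param seed integer random seed.
#' @return list with the subset object `x` and its `labels`.
#' @export
subsampleCells <- function(x, labels = NULL,
                           mode = c("size", "imbalance"), level,
                           seed = 1L) {
    mode <- match.arg(mode)
    if (is.null(labels)) {
        if (!is(x, "SummarizedExperiment") ||
            !"cell_type" %in% colnames(SummarizedExperiment::colData(x)))
            stop("supply 'labels' (no colData$cell_type found)")
        labels <- SummarizedExperiment::colData(x)$cell_type
    }
    labels <- as.character(labels)
    n <- length(labels)
    seed <- .checkSeed(seed)
    set.seed(seed)
    if (mode == "size") {
        nKeep <- if (level <= 1) floor(level * n) else as.integer(level)
        if (nKeep < length(unique(labels)))
            stop("subsampling to ", nKeep, " cells leaves fewer cells ",
                 "than cell types")
        keep <- sort(sample.int(n, nKeep))
    } else {
        counts <- table(labels)
        lv <- names(counts)
        counts <- as.numeric(counts)
        iOf <- function(ct) {
            p <- ct[ct > 0] / sum(ct)
            1 + sum(p * log(p)) / log(length(ct))
        }
        target <- function(t)
            pmax(1, pmin(counts, round((1 - t) * counts +
                                       t * min(counts))))
        if (level >= iOf(counts)) {
            keep <- seq_len(n)
        } else {
            lo <- 0; hi <- 1
            for (i in 1:60) {
                mid <- (lo + hi) / 2
                if (iOf(target(mid)) > level) lo <- mid else hi <- mid
            }
            ct <- target(hi)
            keep <- sort(unlist(lapply(seq_along(lv), function(i) {
                idx <- which(labels == lv[i])
                sample(idx, ct[i])
            })))
        }
    }
    list(x = x[, keep], labels = labels[keep])
}

#' Per-cluster differentially accessible peaks
#'
#' Ranks peaks for each cluster by a group-mean-difference score (mean
#' accessibility inside the cluster minus mean outside) and returns the
#' top `topN` per cluster. On the noiseless truth layer of a simulation
#' with disjoint marker blocks, this recovers the planted markers.
#'
#' @param x binary/count peak-by-cell matrix or `SingleCellExperiment`
#'   (assay `"truth"` preferred, else `"counts"`).
#' @param labels cluster labels (default `colData(x)$cell_type`).
#' @param topN peaks per cluster (default 3000).
#' @return named list of per-cluster peak index vectors, with attribute
#'   `"unionSize"` (size of the union of the lists).
#' @export
differentialPeaks <- function(x, labels = NULL, topN = 3000L) {
    if (is(x, "SummarizedExperiment")) {
        if (is.null(labels))
            labels <- SummarizedExperiment::colData(x)$cell_type
        nm <- SummarizedExperiment::assayNames(x)
        m <- SummarizedExperiment::assay(
            x, if ("truth" %in% nm) "truth" else "counts")
    } else {
        m <- x
    }
    if (is.null(labels)) stop("'labels' required")
    labels <- as.character(labels)
    topN <- min(as.integer(topN), nrow(m))
    rs <- function(mm) if (is(mm, "sparseMatrix")) Matrix::rowSums(mm)
                       else rowSums(mm)
    total <- rs(m)
    nTot <- ncol(m)
    out <- lapply(unique(labels), function(l) {
        sel <- labels == l
        inSum <- rs(m[, sel, drop = FALSE])
        score <- inSum / sum(sel) - (total - inSum) / (nTot - sum(sel))
        order(score, decreasing = TRUE)[seq_len(topN)]
    })
    names(out) <- unique(labels)
    attr(out, "unionSize") <- length(Reduce(union, out))
    out
}
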