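# Reference construction: bulk scaling, pseudo-bulk aggregation by
# labels, and self-reference via community detection on the data itself.

#' Extract a projection basis from reference profiles
#'
#' Conventional NMF of a reference matrix (peaks x samples); the
#' resulting `W` factor is the basis `P` that anchors `k1` components of
#' the reference-anchored model.
#'
#' @param ref non-negative peaks x samples matrix.
#' @param k1 number of components; must not exceed the number of
#'   samples.
#' @param seed integer random seed.
#' @return m x k1 non-negative basis matrix.
#' @export
nmfReference <- function(ref, k1, seed = 1L) {
    ref <- .denseMatrix(ref)
    if (k1 > ncol(ref))
        stop("'k1' (", k1, ") exceeds the number of reference samples (",
             ncol(ref), ")")
    runNMF(ref, k1, seed = seed)$W
}

#' Align a target and a reference on their common peaks
#'
#' Reference profiles must cover exactly the peaks of the (filtered)
#' target matrix, identically ordered. This helper intersects the two
#' peak sets (exact interval-identifier match), reports how many peaks
#' were dropped on each side, and returns both objects subset to the
#' common peaks in the target's order.
#'
#' @param x target (`SingleCellExperiment` or matrix with rownames).
#' @param ref reference (`SummarizedExperiment` or matrix with
#'   rownames).
#' @return list with elements `x` and `ref`.
#' @export
alignPeakSets <- function(x, ref) {
    xIds <- if (is(x, "SummarizedExperiment"))
        peakIds(SummarizedExperiment::rowRanges(x)) else rownames(x)
    rIds <- if (is(ref, "SummarizedExperiment"))
        peakIds(SummarizedExperiment::rowRanges(ref)) else rownames(ref)
    common <- intersect(xIds, rIds)
    if (!length(common))
        stop("no peaks in common between target and reference")
    dropX <- length(xIds) - length(common)
    dropR <- length(rIds) - length(common)
    if (dropX || dropR)
        message("alignPeakSets: dropped ", dropX, " target and ", dropR,
                " reference peak(s) without a match")
    common <- xIds[xIds %in% common]      # keep target order
    list(x = x[match(common, xIds), ],
         ref = ref[match(common, rIds), , drop = FALSE])
}

#' Build a reference from bulk profiles
#'
#' Scales each bulk sample's peak counts by its total mapped reads
#' (per-million), making samples of different sequencing depth
#' comparable.
#'
#' @param bulk non-negative peaks x samples count matrix aligned to the
#'   target peaks.
#' @param totalMappedReads numeric vector, one positive total per
#'   sample; defaults to the column sums of `bulk`.
#' @return scaled reference matrix (reads per million), with attribute
#'   `provenance = "bulk"`.
#' @export
buildReferenceFromBulk <- function(bulk, totalMappedReads = NULL) {
    bulk <- .denseMatrix(bulk)
    if (is.null(totalMappedReads)) totalMappedReads <- colSums(bulk)
    if (length(totalMappedReads) != ncol(bulk))
        stop("'totalMappedReads' must have one value per sample")
    if (any(totalMappedReads <= 0))
        stop("sample(s) with zero total mapped reads")
    out <- sweep(bulk, 2L, totalMappedReads / 1e6, "/")
    attr(out, "provenance") <- "bulk"
    out
}

#' Build a pseudo-bulk reference from labeled cells
#'
#' Sums the raw counts of every peak over the cells of each label,
#' producing one reference column per cell type.
#'
#' @param x `SingleCellExperiment` (assay `"counts"`) or matrix.
#' @param labels cell labels, one per column of `x`.
#' @param assay assay to aggregate for `SingleCellExperiment` input.
#' @return peaks x types matrix of per-type count sums, with attribute
#'   `provenance = "pseudo-bulk-labels"`; empty label classes are
#'   dropped with a warning.
#' @export
buildPseudobulk <- function(x, labels, assay = "counts") {
    m <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, assay) else x
    if (length(labels) != ncol(m))
        stop("'labels' must have one entry per cell")
    lv <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
    labels <- as.character(labels)
    empty <- !lv %in% labels
    if (any(empty)) {
        warning(sum(empty), " empty label class(es) dropped", call. = FALSE)
        lv <- lv[!empty]
    }
    cols <- vapply(lv, function(l) {
        sel <- which(labels == l)
        if (is(m, "sparseMatrix")) Matrix::rowSums(m[, sel, drop = FALSE])
        else rowSums(m[, sel, drop = FALSE])
    }, numeric(nrow(m)))
    out <- matrix(cols, nrow = nrow(m), dimnames = list(rownames(m), lv))
    attr(out, "provenance") <- "pseudo-bulk-labels"
    out
}

#' Build a self-reference by clustering the data itself
#'
#' When no external reference exists, the data can serve as its own:
#' cells are clustered by Louvain community detection on a
#' nearest-neighbor graph of their 50-dimensional principal-component
#' representation (of the TF-IDF layer), and raw counts are summed per
#' cluster.
#'
#' @param x `SingleCellExperiment` with `"counts"` (and ideally
#'   `"tfidf"`) assays, or a matrix (used for both clustering and
#'   aggregation).
#' @param resolution Louvain resolution (default 1, the common
#'   single-cell default).
#' @param nNeighbors neighbors in the graph (default 15).
#' @param nComponents principal components used (default 50, clamped).
#' @param seed integer random seed.
#' @return peaks x clusters matrix of per-cluster count sums, attribute
#'   `provenance = "self-reference"`; a single-cluster outcome produces
#'   a warning but still a (one-column) reference.
#' @export
buildSelfReference <- function(x, resolution = 1, nNeighbors = 15L,
                               nComponents = 50L, seed = 1L) {
    emb <- if (is(x, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(x)
        pcaReduce(SummarizedExperiment::assay(
            x, if ("tfidf" %in% nm) "tfidf" else "counts"),
            nComponents = nComponents)
    } else {
        pcaReduce(x, nComponents = nComponents)
    }
    g <- .knnGraph(emb, nNeighbors)
    set.seed(.checkSeed(seed))
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- paste0("cluster_", igraph::membership(cl))
    if (length(unique(labels)) == 1L)
        warning("community detection found a single cluster; reference ",
                "has one column", call. = FALSE)
    out <- buildPseudobulk(x, labels)
    attr(out, "provenance") <- "self-reference"
    out
}
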