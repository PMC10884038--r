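# Peak-level interpretation of the fitted factors: each column of the
# projection matrix W is a program of co-accessible peaks, and the
# matching row of the embedding H says which cells use it.

#' Cell type-specific peaks from a fitted model
#'
#' Identifies the factor component most active in a target cell group
#' (the component whose embedding row has the highest group-mean, or
#' group-median, activation) and returns the peaks with the largest
#' coefficients in the corresponding projection column. Ties are broken
#' by peak order.
#'
#' @param fit an [EnhanceFit-class] (or a list with elements `W`, `H`).
#' @param groups cell labels or cluster assignment, one per cell.
#' @param targetGroup the group of interest (must occur in `groups`).
#' @param topN number of peaks to return (default 100; capped at the
#'   number of peaks).
#' @param summary `"mean"` (default) or `"median"` activation summary.
#' @return data.frame with columns `peak`, `component`, `coefficient`,
#'   `rank` (class `"PeakScoreTable"`).
#' @examples
#' W <- diag(4); H <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1),
#'                          c(0, 0, 0, 0), c(0, 0, 0, 0))
#' rownames(W) <- paste0("chr1:", 0:3 * 100, "-", 0:3 * 100 + 50)
#' specificPeaks(list(W = W, H = H), rep(c("a", "b"), each = 2), "a",
#'               topN = 1)
#' @export
specificPeaks <- function(fit, groups, targetGroup, topN = 100L,
                          summary = c("mean", "median")) {
    summary <- match.arg(summary)
    W <- if (is(fit, "EnhanceFit")) projectionMatrix(fit) else fit$W
    H <- if (is(fit, "EnhanceFit")) cellEmbedding(fit) else fit$H
    groups <- as.character(groups)
    if (length(groups) != ncol(H))
        stop("'groups' must have one entry per cell")
    sel <- groups == targetGroup
    if (!any(sel))
        stop("unknown group: '", targetGroup, "'")
    act <- if (summary == "mean") rowMeans(H[, sel, drop = FALSE])
           else apply(H[, sel, drop = FALSE], 1L, stats::median)
    comp <- which.max(act)
    topN <- min(as.integer(topN), nrow(W))
    ord <- order(W[, comp], decreasing = TRUE)[seq_len(topN)]
    ids <- rownames(W)
    if (is.null(ids)) ids <- paste0("peak_", seq_len(nrow(W)))
    out <- data.frame(peak = ids[ord], component = comp,
                      coefficient = W[ord, comp],
                      rank = seq_len(topN), row.names = NULL)
    class(out) <- c("PeakScoreTable", class(out))
    out
}

#' Background peaks from a fitted model
#'
#' Selects peaks whose mean projection coefficient (row mean of `W`) is
#' closest to the global mean coefficient of `W`: peaks of unremarkable,
#' typical accessibility that serve as a background set for downstream
#' enrichment analyses. Ties are broken by peak order.
#'
#' @param fit an [EnhanceFit-class] (or a list with element `W`, or a
#'   matrix `W`).
#' @param nBackground number of background peaks (default 1000; capped
#'   at the number of peaks with a warning).
#' @return data.frame with columns `peak`, `component` (NA), the row
#'   mean as `coefficient`, and `rank` by closeness to the global mean.
#' @export
backgroundPeaks <- function(fit, nBackground = 1000L) {
    W <- if (is(fit, "EnhanceFit")) projectionMatrix(fit)
         else if (is.list(fit)) fit$W else fit
    nBackground <- as.integer(nBackground)
    if (nBackground > nrow(W)) {
        warning("'nBackground' exceeds the number of peaks; capped at ",
                nrow(W), call. = FALSE)
        nBackground <- nrow(W)
    }
    rowMean <- rowMeans(W)
    closeness <- abs(rowMean - mean(W))
    ord <- order(closeness)[seq_len(nBackground)]
    ids <- rownames(W)
    if (is.null(ids)) ids <- paste0("peak_", seq_len(nrow(W)))
    out <- data.frame(peak = ids[ord], component = NA_integer_,
                      coefficient = rowMean[ord],
                      rank = seq_len(nBackground), row.names = NULL)
    class(out) <- c("PeakScoreTable", class(out))
    out
}

#' Overlap between two peak score tables
#'
#' Specific and background peak sets are meant to be disjoint when the
#' coefficients separate them; when they do not, the overlap should be
#' known, not silent. Returns the shared peak identifiers.
#'
#' @param a,b `PeakScoreTable` data.frames (or character vectors).
#' @return character vector of shared peaks (possibly empty); a message
#'   reports the overlap size when nonzero.
#' @export
peakTableOverlap <- function(a, b) {
    pa <- if (is.data.frame(a)) a$peak else as.character(a)
    pb <- if (is.data.frame(b)) b$peak else as.character(b)
    ov <- intersect(pa, pb)
    if (length(ov))
        message(length(ov), " peak(s) shared between the two sets")
    ov
}

#' Export a peak score table as BED6 (+ score TSV)
#'
#' Writes the selected peaks as a BED6 file (name = rank, score = the
#' coefficient scaled to 0-1000, strand ".") for downstream enrichment
#' tools, plus an optional TSV with the full score table. Intervals
#' round-trip through [parsePeakIntervals()].
#'
#' @param tbl a `PeakScoreTable` from [specificPeaks()] or
#'   [backgroundPeaks()].
#' @param path output BED file.
#' @param scoreTable optional path for the TSV score table.
#' @return `path`, invisibly.
#' @export
exportPeaksBED <- function(tbl, path, scoreTable = NULL) {
    gr <- parsePeakIntervals(tbl$peak)
    coef <- tbl$coefficient
    rng <- range(coef)
    score <- if (diff(rng) > 0)
        round(1000 * (coef - rng[1L]) / diff(rng)) else rep(0L, length(coef))
    bed <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = S4Vectors::mcols(gr)$bedStart,
        end = S4Vectors::mcols(gr)$bedEnd,
        name = tbl$rank, score = score, strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(scoreTable))
        utils::write.table(tbl, scoreTable, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    invisible(path)
}
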