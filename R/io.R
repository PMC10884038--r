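#' Parse peak intervals into genomic ranges
#'
#' Peaks are genomic intervals of open chromatin. Two textual encodings are
#' accepted: `"chr:start-end"` strings (one per peak) and 3-column BED
#' (chrom, start, end). Both are interpreted in the 0-based half-open BED
#' convention; strand is ignored (accessibility is strandless). The
#' returned `GRanges` keeps BED coordinates in `mcols()$bedStart` /
#' `bedEnd` so that writing round-trips exactly.
#'
#' @param x a character vector of `"chr:start-end"` identifiers, or a
#'   data.frame with columns chrom/start/end.
#' @return a [GenomicRanges::GRanges] with one range per peak and the
#'   original identifier as names.
#' @examples
#' parsePeakIntervals(c("chr1:0-500", "chr1:1000-1500"))
#' @export
parsePeakIntervals <- function(x) {
    if (is.data.frame(x)) {
        chrom <- as.character(x[[1L]])
        start0 <- as.integer(x[[2L]])
        end0 <- as.integer(x[[3L]])
    } else {
        x <- as.character(x)
        ok <- grepl("^[^:]+:[0-9]+-[0-9]+$", x)
        if (!all(ok))
            stop("malformed peak identifier(s), expected 'chr:start-end': ",
                 paste(utils::head(x[!ok], 3L), collapse = ", "))
        chrom <- sub(":.*$", "", x)
        rest <- sub("^[^:]+:", "", x)
        start0 <- as.integer(sub("-.*$", "", rest))
        end0 <- as.integer(sub("^.*-", "", rest))
    }
    if (any(end0 <= start0))
        stop("peak intervals must have end > start (0-based half-open)")
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
    )
    S4Vectors::mcols(gr)$bedStart <- start0
    S4Vectors::mcols(gr)$bedEnd <- end0
    names(gr) <- paste0(chrom, ":", start0, "-", end0)
    gr
}

#' Format peak ranges back to "chr:start-end" identifiers
#'
#' @param gr a `GRanges` as produced by [parsePeakIntervals()], or a
#'   character vector (returned unchanged).
#' @return character vector of 0-based half-open peak identifiers.
#' @export
peakIds <- function(gr) {
    if (is.character(gr)) return(gr)
    if (!is.null(names(gr)) && all(nzchar(names(gr)))) return(names(gr))
    paste0(as.character(GenomicRanges::seqnames(gr)), ":",
           GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr))
}

.readPeakFile <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl("\t", first)) {
        df <- utils::read.delim(path, header = FALSE,
                                stringsAsFactors = FALSE)
        parsePeakIntervals(df[, 1:3])
    } else {
        parsePeakIntervals(readLines(path))
    }
}

.findFile <- function(dir, candidates) {
    for (f in candidates) {
        p <- file.path(dir, f)
        if (file.exists(p)) return(p)
    }
    NULL
}

#' Read a peak-by-cell accessibility matrix
#'
#' Reads single-cell chromatin accessibility data into a
#' [SingleCellExperiment::SingleCellExperiment] whose rows are peaks
#' (carried as `rowRanges`) and columns are cell barcodes. Two on-disk
#' layouts are supported: a 10x-style Matrix Market directory (matrix.mtx
#' + peaks file + barcodes.tsv) and a dense TSV with a header row of
#' barcodes and a first column of peak identifiers.
#'
#' @param path directory (Matrix Market layout) or TSV file.
#' @param format `"auto"` (directory implies `"mtx"`, file implies
#'   `"tsv"`), `"mtx"` or `"tsv"`.
#' @param matrixFile,peaksFile,barcodesFile optional explicit file names
#'   inside `path` for the Matrix Market layout.
#' @return a `SingleCellExperiment` with assay `"counts"` (sparse),
#'   `rowRanges` holding peak intervals, and the preprocessing layer tag
#'   set to `"raw"`.
#' @seealso [writePeakMatrix()], [filterPeaks()], [tfidfTransform()]
#' @export
readPeakMatrix <- function(path, format = c("auto", "mtx", "tsv"),
                           matrixFile = NULL, peaksFile = NULL,
                           barcodesFile = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (dir.exists(path)) "mtx" else "tsv"
    if (format == "mtx") {
        if (!dir.exists(path)) stop("not a directory: ", path)
        mf <- if (is.null(matrixFile)) .findFile(path, "matrix.mtx")
              else file.path(path, matrixFile)
        pf <- if (is.null(peaksFile))
                  .findFile(path, c("peaks.bed", "peaks.tsv", "peaks.txt",
                                    "features.tsv"))
              else file.path(path, peaksFile)
        bf <- if (is.null(barcodesFile)) .findFile(path, "barcodes.tsv")
              else file.path(path, barcodesFile)
        for (p in list(mf = mf, pf = pf, bf = bf))
            if (is.null(p) || !file.exists(p))
                stop("missing input file in ", path,
                     " (need matrix.mtx, a peaks file and barcodes.tsv)")
        m <- as(Matrix::readMM(mf) * 1, "CsparseMatrix")
        peaks <- .readPeakFile(pf)
        barcodes <- readLines(bf)
        if (length(peaks) != nrow(m))
            stop("dimension mismatch: ", basename(pf), " has ",
                 length(peaks), " peaks but ", basename(mf), " has ",
                 nrow(m), " rows")
        if (length(barcodes) != ncol(m))
            stop("dimension mismatch: ", basename(bf), " has ",
                 length(barcodes), " barcodes but ", basename(mf),
                 " has ", ncol(m), " columns")
    } else {
        if (!file.exists(path)) stop("missing input file: ", path)
        df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                                stringsAsFactors = FALSE)
        peaks <- parsePeakIntervals(df[[1L]])
        m <- as(as.matrix(df[, -1L, drop = FALSE]), "CsparseMatrix")
        barcodes <- colnames(df)[-1L]
    }
    if (any(m@x < 0))
        stop("negative entries found; accessibility counts must be >= 0")
    if (anyDuplicated(barcodes))
        stop("duplicate cell barcodes in input")
    dimnames(m) <- list(names(peaks), barcodes)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), rowRanges = peaks)
    .setLayer(sce, "raw")
}

#' Write a peak-by-cell matrix
#'
#' Inverse of [readPeakMatrix()]: writes either a Matrix Market directory
#' (matrix.mtx + peaks.bed + barcodes.tsv) or a dense TSV. The assay
#' written is `"counts"` unless another is named.
#'
#' @param x a `SingleCellExperiment` (or matrix with dimnames).
#' @param path output directory (`format = "mtx"`) or file (`"tsv"`).
#' @param format `"mtx"` (sparse) or `"tsv"` (dense).
#' @param assay assay name to write when `x` is a
#'   `SingleCellExperiment`.
#' @return `path`, invisibly.
#' @export
writePeakMatrix <- function(x, path, format = c("mtx", "tsv"),
                            assay = "counts") {
    format <- match.arg(format)
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, assay)
        ids <- peakIds(SummarizedExperiment::rowRanges(x))
        barcodes <- colnames(x)
    } else {
        m <- x
        ids <- rownames(x)
        barcodes <- colnames(x)
    }
    if (format == "mtx") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(as(as(m * 1, "CsparseMatrix"), "generalMatrix"),
                        file.path(path, "matrix.mtx"))
        gr <- parsePeakIntervals(ids)
        utils::write.table(
            data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = S4Vectors::mcols(gr)$bedStart,
                       end = S4Vectors::mcols(gr)$bedEnd),
            file.path(path, "peaks.bed"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
        writeLines(barcodes, file.path(path, "barcodes.tsv"))
    } else {
        df <- data.frame(peak = ids, as.matrix(m), check.names = FALSE)
        colnames(df) <- c("peak", barcodes)
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read cell-type labels
#'
#' Reads a TSV of (barcode, type) pairs, or a single column of types, and
#' orders them to match a matrix's barcodes.
#'
#' @param path TSV file; one or two columns, no header required (a header
#'   line `barcode<TAB>...` is detected and skipped).
#' @param barcodes optional character vector; when given, labels are
#'   reordered to match and every barcode must be present exactly once.
#' @return a named character vector of cell-type labels.
#' @export
readCellLabels <- function(path, barcodes = NULL) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) && df[1, 1] %in% c("barcode", "cell", "barcodes"))
        df <- df[-1L, , drop = FALSE]
    if (ncol(df) >= 2L) {
        labels <- stats::setNames(as.character(df[[2L]]),
                                  as.character(df[[1L]]))
    } else {
        labels <- as.character(df[[1L]])
        if (!is.null(barcodes)) names(labels) <- barcodes
    }
    if (!is.null(barcodes) && !is.null(names(labels))) {
        if (anyDuplicated(names(labels)))
            stop("duplicate barcodes in label file")
        missing <- setdiff(barcodes, names(labels))
        if (length(missing))
            stop("labels missing for ", length(missing), " barcode(s), e.g. ",
                 missing[1L])
        labels <- labels[barcodes]
    }
    labels
}

#' Filter rarely accessible peaks
#'
#' Removes peaks observed in fewer than a given fraction of cells. A peak
#' is kept iff its number of cells with a nonzero count is at least
#' `ceiling(minCellFraction * n)`; the boundary is inclusive, so with the
#' default 1% threshold on 200 cells a peak must be open in >= 2 cells.
#' The operation is idempotent at a fixed threshold.
#'
#' @param x a `SingleCellExperiment` with a `"counts"` assay, or a
#'   matrix.
#' @param minCellFraction fraction of cells in `[0, 1]`; default 0.01.
#' @param ... unused.
#' @return the filtered object (peak subset, original order preserved),
#'   layer tag `"filtered"`.
#' @examples
#' sim <- simulateAccessibility(nClusters = 2, cellsPerCluster = 20,
#'                              markerPeaksPerCluster = 50, seed = 1)
#' filterPeaks(sim)
#' @export
setMethod("filterPeaks", "ANY", function(x, minCellFraction = 0.01, ...) {
    m <- x
    keep <- .peakKeep(m, minCellFraction)
    m[keep, , drop = FALSE]
})

#' @rdname filterPeaks
#' @export
setMethod("filterPeaks", "SummarizedExperiment",
    function(x, minCellFraction = 0.01, ...) {
        keep <- .peakKeep(SummarizedExperiment::assay(x, "counts"),
                          minCellFraction)
        .setLayer(x[keep, ], "filtered")
    })

.peakKeep <- function(m, minCellFraction) {
    if (minCellFraction < 0 || minCellFraction > 1)
        stop("'minCellFraction' must lie in [0, 1]")
    n <- ncol(m)
    nCells <- if (is(m, "sparseMatrix")) Matrix::rowSums(m > 0)
              else rowSums(m > 0)
    keep <- nCells >= ceiling(minCellFraction * n)
    if (!any(keep))
        stop("all peaks removed; lower 'minCellFraction'")
    keep
}

#' TF-IDF transformation of accessibility counts
#'
#' Reweights the peak-by-cell matrix by term frequency-inverse document
#' frequency: each entry is divided by its cell's total count (term
#' frequency, normalizing sequencing depth) and multiplied by
#' `log(n / a_i)` where `a_i` measures how commonly peak i is open
#' (inverse document frequency, down-weighting ubiquitous peaks).
#'
#' By default `a_i` is the number of cells in which peak i is open
#' (`idfOnBinarized = TRUE`), which guarantees a non-negative result as
#' required by the downstream non-negative factorization. Setting
#' `idfOnBinarized = FALSE` uses the raw count total, which can produce
#' negative weights when a peak's total count exceeds the number of
#' cells. On strictly binary input both dialects coincide. Natural
#' logarithms are used.
#'
#' @param x a `SingleCellExperiment` (assay `"counts"`) or matrix.
#' @param idfOnBinarized logical; compute the IDF denominator on
#'   binarized counts (default) or on raw counts.
#' @param ... unused.
#' @return same container with the transformed matrix (assay `"tfidf"`
#'   added for `SingleCellExperiment` input), layer tag `"tfidf"`.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, dimnames = list(c("p1", "p2"), c("c1", "c2")))
#' tfidfTransform(m)
#' @export
setMethod("tfidfTransform", "ANY", function(x, idfOnBinarized = TRUE, ...) {
    .tfidf(x, idfOnBinarized)
})

#' @rdname tfidfTransform
#' @export
setMethod("tfidfTransform", "SummarizedExperiment",
    function(x, idfOnBinarized = TRUE, ...) {
        m <- SummarizedExperiment::assay(x, "counts")
        SummarizedExperiment::assay(x, "tfidf") <-
            .tfidf(m, idfOnBinarized)
        .setLayer(x, "tfidf")
    })

.tfidf <- function(m, idfOnBinarized) {
    n <- ncol(m)
    sparse <- is(m, "sparseMatrix")
    depth <- if (sparse) Matrix::colSums(m) else colSums(m)
    if (any(depth == 0))
        stop("cell(s) with all-zero counts: term frequency undefined for ",
             sum(depth == 0), " column(s)")
    acc <- if (idfOnBinarized) {
        if (sparse) Matrix::rowSums(m > 0) else rowSums(m > 0)
    } else {
        if (sparse) Matrix::rowSums(m) else rowSums(m)
    }
    idf <- ifelse(acc > 0, log(n / acc), 0)
    if (sparse) {
        m <- as(m, "CsparseMatrix")
        tf <- m %*% Matrix::Diagonal(x = 1 / depth)
        out <- Matrix::Diagonal(x = idf) %*% tf
        out <- as(out, "CsparseMatrix")
        dimnames(out) <- dimnames(m)
        Matrix::drop0(out)
    } else {
        sweep(sweep(m, 2L, depth, "/"), 1L, idf, "*")
    }
}
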