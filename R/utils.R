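# Internal helpers shared across modules.

# Current preprocessing layer recorded on a SingleCellExperiment.
.getLayer <- function(x) {
    tag <- S4Vectors::metadata(x)$scEnhanceLayer
    if (is.null(tag)) "raw" else tag
}

.setLayer <- function(x, tag) {
    S4Vectors::metadata(x)$scEnhanceLayer <- tag
    x
}

# Extract a dense base matrix from a SingleCellExperiment assay or any
# matrix-like input. `assay` = NULL picks, in order, tfidf > counts > first.
.denseMatrix <- function(x, assay = NULL) {
    if (is(x, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(x)
        if (is.null(assay)) {
            assay <- if ("tfidf" %in% nm) "tfidf"
                     else if ("counts" %in% nm) "counts" else nm[1L]
        }
        if (!assay %in% nm)
            stop("assay '", assay, "' not found; available: ",
                 paste(nm, collapse = ", "))
        x <- SummarizedExperiment::assay(x, assay)
    }
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
}

# Safe relative difference used by stopping rules and tests.
.relDiff <- function(a, b) abs(a - b) / max(abs(b), 1e-12)

.checkSeed <- function(seed) {
    seed <- as.integer(seed)
    if (is.na(seed) || seed > .Machine$integer.max - 8L)
        stop("'seed' must be an integer below 2^31 - 8")
    seed
}
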