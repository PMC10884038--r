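#' Jaccard similarity between cells
#'
#' Computes the pairwise Jaccard index between the binarized
#' accessibility profiles of all cells:
#' `J(i, j) = |supp(i) n supp(j)| / |supp(i) u supp(j)|`. This is the
#' standard initialization of the cell-to-cell similarity matrix: sparse
#' binary profiles make it a cheap and robust first guess at which cells
#' resemble each other. The result is symmetric with unit diagonal; it is
#' not column-normalized here (the fit normalizes the initial matrix).
#'
#' @param x a `SingleCellExperiment`, sparse or dense peak-by-cell
#'   matrix; entries are binarized at > 0.
#' @param assay assay to use for `SingleCellExperiment` input (default
#'   `"counts"`).
#' @return dense n x n matrix of Jaccard similarities.
#' @examples
#' m <- cbind(a = c(1, 1, 0), b = c(1, 0, 1))
#' jaccardSimilarity(m)   # off-diagonal = 1/3
#' @export
jaccardSimilarity <- function(x, assay = "counts") {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, assay)
    B <- if (is(x, "sparseMatrix")) {
        as(x > 0, "CsparseMatrix") * 1
    } else {
        (as.matrix(x) > 0) * 1
    }
    sizes <- if (is(B, "sparseMatrix")) Matrix::colSums(B) else colSums(B)
    if (any(sizes == 0))
        stop("cell(s) with empty support: Jaccard similarity undefined for ",
             sum(sizes == 0), " cell(s)")
    inter <- as.matrix(Matrix::crossprod(B))
    uni <- outer(sizes, sizes, "+") - inter
    Z <- inter / uni
    dimnames(Z) <- list(colnames(x), colnames(x))
    Z
}

#' Sample the random binary mask
#'
#' The enhancement objective Hadamard-multiplies the similarity matrix by
#' a fixed random binary matrix so that similar cells are not forced onto
#' entirely identical enhanced profiles, which would erase genuine
#' cell-to-cell heterogeneity. Entries are i.i.d. Bernoulli(`prob`); the
#' mask is sampled once per fit and held fixed so the objective is well
#' defined during optimization.
#'
#' @param n number of cells.
#' @param prob Bernoulli success probability in (0, 1]; `prob = 0` is
#'   rejected because it annihilates the similarity term.
#' @param seed integer random seed.
#' @return n x n matrix of 0/1 values.
#' @examples
#' sampleMask(4, prob = 1, seed = 1)   # all ones
#' @export
sampleMask <- function(n, prob, seed = 1L) {
    if (n < 1L) stop("'n' must be >= 1")
    if (prob <= 0 || prob > 1)
        stop("'prob' must lie in (0, 1]; prob = 0 would annihilate the ",
             "similarity term")
    seed <- .checkSeed(seed)
    set.seed(seed)
    matrix(stats::rbinom(n * n, 1L, prob), n, n)
}
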