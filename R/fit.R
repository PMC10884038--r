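# Iterative optimization: projected gradient descent with closed-form
# exact line search for W and Z and a backtracked step for H. One engine
# serves both the core model (k1 = 0) and the reference-anchored variant
# (k1 > 0, anchored columns tied to the basis P).

.fitEngine <- function(X, Bsrc, params, P = NULL) {
    k <- params@k
    isRef <- is(params, "RefEnhanceParams")
    k1 <- if (isRef) params@k1 else 0L
    alpha <- if (isRef) params@alpha else 0
    if (k1 > 0L && is.null(P))
        stop("reference basis P required when k1 > 0")
    lambda <- params@lambda; g1 <- params@gamma1; g2 <- params@gamma2
    m <- nrow(X); n <- ncol(X)
    if (k > min(m, n))
        stop("'k' (", k, ") exceeds min(dim(X)) = ", min(m, n))
    k2 <- k - k1
    idx1 <- seq_len(k1)

    ## ---- initialization: Jaccard similarity, conventional NMF, mask.
    ## The full embedding comes from NMF of the target (random embedding
    ## rows would pollute Z through the lambda-weighted consistency
    ## term); for a reference fit the k1 leading projection columns are
    ## replaced by the reference basis, rescaled to the NMF column scale
    ## (NMF factor scale is non-identifiable, so this is a free choice).
    Z <- jaccardSimilarity(Bsrc)
    Z <- sweep(Z, 2L, colSums(Z), "/")
    nmf <- runNMF(X, k, seed = params@seed)
    H <- nmf$H
    if (k1 > 0L) {
        scaleTo <- mean(sqrt(colSums(nmf$W^2)))
        pNorm <- sqrt(colSums(P^2))
        pNorm[pNorm == 0] <- 1
        P <- P * rep(scaleTo / pNorm, each = m)
        W <- cbind(P, nmf$W[, seq.int(k1 + 1L, k), drop = FALSE])
    } else {
        W <- nmf$W
    }
    R <- sampleMask(n, params@maskP, seed = params@seed + 1L)

    ## ---- caches (X enters only through G = X'X and W'X products)
    G <- crossprod(X)
    ZR <- Z * R
    GZR <- G %*% ZR
    WtX <- crossprod(W, X)

    alphaPen <- function(W) {
        if (k1 > 0L) alpha * sum((P - W[, idx1, drop = FALSE])^2) else 0
    }
    evalLoss <- function(W, H, Z, ZR, GZR, WtX) {
        sum(GZR * ZR) - 2 * sum((WtX %*% ZR) * H) +
            sum(crossprod(W) * tcrossprod(H)) +
            lambda * sum((Z - crossprod(H))^2) +
            g1 * sum(W * W) + g2 * sum(H * H) + alphaPen(W)
    }

    trace <- numeric(params@maxIter + 1L)
    trace[1L] <- evalLoss(W, H, Z, ZR, GZR, WtX)
    converged <- FALSE
    nSkip <- c(W = 0L, Z = 0L)
    iters <- 0L

    for (t in seq_len(params@maxIter)) {
        Fprev <- trace[t]
        Fcur <- Fprev

        ## ---- W: exact line minimizer + non-negativity projection
        HHt <- tcrossprod(H)
        XZRHt <- X %*% (ZR %*% t(H))
        D1 <- -2 * XZRHt + 2 * W %*% HHt + 2 * g1 * W
        if (k1 > 0L)
            D1[, idx1] <- D1[, idx1, drop = FALSE] +
                2 * alpha * (W[, idx1, drop = FALSE] - P)
        num <- sum(D1 * (W %*% HHt)) - sum(D1 * XZRHt) + g1 * sum(D1 * W)
        den <- sum(crossprod(D1) * HHt) + g1 * sum(D1 * D1)
        if (k1 > 0L) {
            D1a <- D1[, idx1, drop = FALSE]
            num <- num + alpha * sum(D1a * (W[, idx1, drop = FALSE] - P))
            den <- den + alpha * sum(D1a * D1a)
        }
        if (den > 1e-300) {
            if (num <= 0) {
                nSkip["W"] <- nSkip["W"] + 1L
            } else {
                delta <- num / den
                for (h in 1:30) {
                    Wn <- pmax(W - delta * D1, 0)
                    WtXn <- crossprod(Wn, X)
                    Fn <- evalLoss(Wn, H, Z, ZR, GZR, WtXn)
                    if (Fn <= Fcur) {
                        W <- Wn; WtX <- WtXn; Fcur <- Fn
                        break
                    }
                    delta <- delta / 2
                }
            }
        }

        ## ---- Z: exact line minimizer + projection
        HtH <- crossprod(H)
        XtWH <- crossprod(WtX, H)
        D2 <- 2 * GZR * R - 2 * XtWH * R + 2 * lambda * Z - 2 * lambda * HtH
        DR <- D2 * R
        num <- sum(DR * GZR) - sum(DR * XtWH) +
            lambda * sum(D2 * (Z - HtH))
        den <- sum((G %*% DR) * DR) + lambda * sum(D2 * D2)
        if (den > 1e-300) {
            if (num <= 0) {
                nSkip["Z"] <- nSkip["Z"] + 1L
            } else {
                delta <- num / den
                for (h in 1:30) {
                    Zn <- pmax(Z - delta * D2, 0)
                    ZRn <- Zn * R
                    GZRn <- G %*% ZRn
                    Fn <- evalLoss(W, H, Zn, ZRn, GZRn, WtX)
                    if (Fn <= Fcur) {
                        Z <- Zn; ZR <- ZRn; GZR <- GZRn; Fcur <- Fn
                        break
                    }
                    delta <- delta / 2
                }
            }
        }

        ## ---- H: backtracked projected step
        WtXZR <- WtX %*% ZR
        WtW <- crossprod(W)
        D3 <- -2 * WtXZR + 2 * WtW %*% H -
            2 * lambda * H %*% (Z + t(Z)) +
            4 * lambda * tcrossprod(H) %*% H + 2 * g2 * H
        dataC <- sum(GZR * ZR) + g1 * sum(W * W) + alphaPen(W)
        delta <- params@delta3Init
        while (delta >= 1e-10) {
            Hn <- pmax(H - delta * D3, 0)
            Fn <- dataC - 2 * sum(WtXZR * Hn) +
                sum(WtW * tcrossprod(Hn)) +
                lambda * sum((Z - crossprod(Hn))^2) + g2 * sum(Hn * Hn)
            if (Fn < Fcur) {
                H <- Hn; Fcur <- Fn
                break
            }
            delta <- delta / 2
        }

        iters <- t
        trace[t + 1L] <- Fcur
        dd <- abs(Fcur - Fprev)
        if (params@stopMode == "relative") dd <- dd / max(Fprev, 1e-12)
        if (dd < params@tol) {
            converged <- TRUE
            break
        }
    }

    if (any(nSkip > 0L))
        warning("skipped non-descent updates (W: ", nSkip["W"],
                ", Z: ", nSkip["Z"], ")", call. = FALSE)

    ## output similarity: columns renormalized to sum to 1
    cs <- colSums(Z)
    if (any(cs == 0)) {
        warning("all-zero similarity column(s) renormalized to uniform",
                call. = FALSE)
        Z[, cs == 0] <- 1 / n
        cs <- colSums(Z)
    }
    Z <- sweep(Z, 2L, cs, "/")

    dimnames(W) <- list(rownames(X), NULL)
    dimnames(H) <- list(NULL, colnames(X))
    dimnames(Z) <- list(colnames(X), colnames(X))
    new("EnhanceFit", W = W, H = H, Z = Z,
        lossTrace = trace[seq_len(iters + 1L)], nIter = iters,
        converged = converged, params = params,
        referenceBasis = if (k1 > 0L) P else matrix(0, nrow(X), 0L))
}

.fitInputs <- function(x, assay) {
    if (is(x, "SummarizedExperiment")) {
        nm <- SummarizedExperiment::assayNames(x)
        use <- if (assay %in% nm) assay else NULL
        X <- .denseMatrix(x, use)
        # Jaccard initialization binarizes the raw counts when available
        # (TF-IDF zeroes ubiquitously open peaks, which would distort
        # supports); otherwise the fitted layer itself.
        Bsrc <- if ("counts" %in% nm)
            SummarizedExperiment::assay(x, "counts") else X
    } else {
        X <- .denseMatrix(x)
        Bsrc <- X
    }
    if (min(X) < 0)
        stop("input matrix has negative entries; the model requires ",
             "X >= 0 (use the binarized-IDF TF-IDF dialect)")
    list(X = X, Bsrc = Bsrc)
}

#' Fit the similarity-regularized enhancement model
#'
#' Minimizes
#' `||X (Z o R) - W H||_F^2 + lambda ||Z - H'H||_F^2 + gamma1 ||W||_F^2 +
#' gamma2 ||H||_F^2` over non-negative `W`, `H`, `Z`, where `R` is a
#' fixed random binary mask. The similarity matrix is initialized from
#' the Jaccard index of binarized profiles (column-normalized), the
#' factor pair from conventional NMF, and the mask is drawn once. Each
#' iteration updates `W` and `Z` by an exact closed-form line search
#' followed by projection onto the non-negative orthant (the step is
#' halved if the projection breaks descent, and skipped with a warning if
#' the line minimizer is non-positive), and `H` by a backtracked
#' projected gradient step. Iteration stops when the relative loss change
#' drops below `tol` or `maxIter` is reached. The loss trace is
#' non-increasing by construction.
#'
#' @param x a `SingleCellExperiment` carrying a `"tfidf"` assay (see
#'   [tfidfTransform()]), or a non-negative peak-by-cell matrix.
#' @param params an [EnhanceParams-class] object; see [enhanceParams()].
#' @param assay assay to fit when `x` is a `SingleCellExperiment`
#'   (default `"tfidf"`).
#' @return an [EnhanceFit-class]; the similarity matrix is returned with
#'   columns renormalized to sum to 1.
#' @examples
#' sim <- simulateAccessibility(nClusters = 2, cellsPerCluster = 15,
#'                              markerPeaksPerCluster = 40, seed = 1)
#' x <- tfidfTransform(filterPeaks(sim))
#' fit <- fitEnhance(x, enhanceParams(k = 2, maxIter = 5, seed = 1))
#' fit
#' @seealso [fitEnhanceRef()] for the reference-anchored variant,
#'   [enhanceMatrix()] to produce the enhanced matrix.
#' @export
fitEnhance <- function(x, params, assay = "tfidf") {
    inp <- .fitInputs(x, assay)
    .fitEngine(inp$X, inp$Bsrc, params, NULL)
}

#' Fit the reference-anchored enhancement model
#'
#' Variant of [fitEnhance()] in which `k1` of the `k` projection
#' components are anchored to a basis `P` extracted by conventional NMF
#' from reference profiles (bulk or pseudo-bulk) over the same peaks,
#' through an extra penalty `alpha ||P - W1||_F^2`. Equivalently, the
#' projection matrix is `M o W1 + N o W2` with column-block masks `M`
#' (anchored columns) and `N = 1 - M`. With `k1 = 0` the reference is
#' ignored and the fit reduces exactly to the core model.
#'
#' @param x target data as in [fitEnhance()].
#' @param ref reference matrix (peaks x samples): a matrix or
#'   `SummarizedExperiment` whose rownames/peaks match `x` exactly; see
#'   [alignPeakSets()] if they do not.
#' @param params a [RefEnhanceParams-class]; see [refEnhanceParams()].
#' @param assay assay of `x` to fit.
#' @param tfidfReference apply the TF-IDF transformation to the reference
#'   columns before extracting the basis (default TRUE) so the basis
#'   lives on the same scale as the fitted target layer.
#' @return an [EnhanceFit-class] with `referenceBasis` filled in.
#' @examples
#' sim <- simulateAccessibility(nClusters = 2, cellsPerCluster = 15,
#'                              markerPeaksPerCluster = 40, seed = 1)
#' x <- tfidfTransform(filterPeaks(sim))
#' ref <- buildPseudobulk(x, x$cell_type)
#' fit <- fitEnhanceRef(x, ref,
#'     refEnhanceParams(k = 3, k1 = 2, alpha = 1, maxIter = 5, seed = 1))
#' @export
fitEnhanceRef <- function(x, ref, params, assay = "tfidf",
                          tfidfReference = TRUE) {
    if (!is(params, "RefEnhanceParams"))
        stop("'params' must be a RefEnhanceParams object")
    inp <- .fitInputs(x, assay)
    if (params@k1 == 0L) {
        message("k1 = 0: reference ignored, fitting the core model")
        return(.fitEngine(inp$X, inp$Bsrc, params, NULL))
    }
    refM <- if (is(ref, "SummarizedExperiment"))
        .denseMatrix(ref, "counts") else .denseMatrix(ref)
    refIds <- if (is(ref, "SummarizedExperiment"))
        peakIds(SummarizedExperiment::rowRanges(ref)) else rownames(ref)
    xIds <- if (is(x, "SummarizedExperiment"))
        peakIds(SummarizedExperiment::rowRanges(x)) else rownames(x)
    if (!is.null(refIds) && !is.null(xIds) && !identical(refIds, xIds))
        stop("reference and target peak sets differ; align them first ",
             "with alignPeakSets()")
    if (nrow(refM) != nrow(inp$X))
        stop("reference has ", nrow(refM), " peaks but target has ",
             nrow(inp$X))
    if (params@k1 > ncol(refM))
        stop("'k1' (", params@k1, ") exceeds the number of reference ",
             "samples (", ncol(refM), ")")
    P <- nmfReference(if (tfidfReference) .tfidf(refM, TRUE) else refM,
                      params@k1, seed = params@seed + 2L)
    .fitEngine(inp$X, inp$Bsrc, params, P)
}

#' Produce the enhanced matrix
#'
#' Multiplies a source layer by the optimized column-stochastic
#' similarity matrix: each enhanced cell profile is a weighted average of
#' the profiles of its similar cells, filling in dropout zeros. The
#' default source is the TF-IDF layer (the layer the objective was
#' optimized on); `layer = "counts"` uses the raw counts instead.
#'
#' @param x the object passed to [fitEnhance()] (matrix or
#'   `SingleCellExperiment`).
#' @param fit an [EnhanceFit-class], or directly an n x n
#'   column-normalized similarity matrix.
#' @param layer source assay for `SingleCellExperiment` input:
#'   `"tfidf"` (default) or `"counts"`.
#' @return for a `SingleCellExperiment`, the object with an
#'   `"enhanced"` assay added (layer tag `"enhanced"`); for a matrix,
#'   the enhanced matrix.
#' @export
enhanceMatrix <- function(x, fit, layer = c("tfidf", "counts")) {
    layer <- match.arg(layer)
    Z <- if (is(fit, "EnhanceFit")) similarityMatrix(fit) else fit
    if (is(x, "SummarizedExperiment")) {
        src <- SummarizedExperiment::assay(x, layer)
        if (ncol(src) != nrow(Z))
            stop("similarity matrix is ", nrow(Z), " x ", ncol(Z),
                 " but data has ", ncol(src), " cells")
        enh <- as.matrix(src %*% Z)
        dimnames(enh) <- dimnames(src)
        SummarizedExperiment::assay(x, "enhanced") <- enh
        .setLayer(x, "enhanced")
    } else {
        if (ncol(x) != nrow(Z))
            stop("similarity matrix is ", nrow(Z), " x ", ncol(Z),
                 " but data has ", ncol(x), " cells")
        out <- as.matrix(x %*% Z)
        dimnames(out) <- dimnames(x)
        out
    }
}

#' One-call enhancement pipeline
#'
#' Convenience wrapper: filter rare peaks, TF-IDF transform, fit the
#' model (core, or reference-anchored when `ref` is supplied) and attach
#' the enhanced assay.
#'
#' @param x a raw `SingleCellExperiment` (assay `"counts"`).
#' @param k latent dimension; defaults to the number of distinct labels
#'   in `labels` when provided (otherwise it must be given).
#' @param labels optional cell-type labels used only to default `k`.
#' @param ref optional reference matrix; switches to the
#'   reference-anchored model.
#' @param params optional parameter object overriding `k`.
#' @param minCellFraction peak filter threshold.
#' @param ... passed to [enhanceParams()] / [refEnhanceParams()].
#' @return list with components `x` (the processed
#'   `SingleCellExperiment`, assays counts/tfidf/enhanced) and `fit`
#'   (the [EnhanceFit-class]).
#' @examples
#' sim <- simulateAccessibility(nClusters = 2, cellsPerCluster = 15,
#'                              markerPeaksPerCluster = 40, seed = 1)
#' res <- scEnhance(sim, k = 2, maxIter = 5, seed = 1)
#' res$fit
#' @export
scEnhance <- function(x, k = NULL, labels = NULL, ref = NULL,
                      params = NULL, minCellFraction = 0.01, ...) {
    if (is.null(params)) {
        if (is.null(k)) {
            if (is.null(labels))
                stop("supply 'k', 'params', or 'labels' to default k from")
            k <- length(unique(labels))
        }
        params <- if (is.null(ref)) enhanceParams(k = k, ...)
                  else refEnhanceParams(k = k, ...)
    }
    x <- filterPeaks(x, minCellFraction)
    x <- tfidfTransform(x)
    fit <- if (is.null(ref)) fitEnhance(x, params)
           else fitEnhanceRef(x, ref, params)
    x <- enhanceMatrix(x, fit)
    list(x = x, fit = fit)
}

#' Heuristic choice of the latent dimension
#'
#' The recommended way to set `k` is the number of expected cell types
#' (external estimators exist for this). When neither labels nor an
#' estimate are available, this heuristic inspects the eigenvalue decay
#' (eigengap) of the column-normalized Jaccard similarity matrix and
#' returns the gap location. It is a rough fallback, not a substitute
#' for a dedicated cell-type-number estimator, and says so loudly.
#'
#' @param x matrix or `SingleCellExperiment` (binarized internally).
#' @param kMax largest dimension considered.
#' @return integer estimate of `k` (at least 2).
#' @export
estimateK <- function(x, kMax = 15L) {
    Z <- jaccardSimilarity(x)
    Z <- (Z + t(Z)) / 2
    ev <- sort(eigen(Z, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    kMax <- min(kMax, length(ev) - 1L)
    gaps <- ev[seq_len(kMax)] - ev[seq_len(kMax) + 1L]
    kHat <- max(2L, which.max(gaps))
    warning("eigengap heuristic only; prefer setting 'k' to the expected ",
            "number of cell types", call. = FALSE)
    kHat
}
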