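#' Conventional non-negative matrix factorization
#'
#' Minimizes `||X - WH||_F^2` over `W >= 0` (m x k) and `H >= 0` (k x n)
#' by HALS coordinate descent: each factor column (row) has a closed-form
#' non-negative least-squares update, cycled until the relative decrease
#' of the residual stalls. Used to initialize the enhancement model and to
#' extract the projection basis from reference profiles. Deterministic
#' given `seed` (factors are initialized from seeded uniform draws scaled
#' to the data magnitude).
#'
#' @param X non-negative matrix (peaks x cells), dense or sparse.
#' @param k number of components, `2 <= k` is not required here (k = 1 is
#'   legal) but `k <= min(dim(X))` is.
#' @param seed integer random seed.
#' @param maxIter maximum HALS sweeps.
#' @param tol relative change of the residual norm at which to stop.
#' @return list with elements `W` (m x k) and `H` (k x n), both
#'   non-negative, carrying the dimnames of `X`.
#' @examples
#' X <- matrix(runif(30), 6, 5)
#' f <- runNMF(X, k = 2, seed = 1)
#' dim(f$W); dim(f$H)
#' @export
runNMF <- function(X, k, seed = 1L, maxIter = 500L, tol = 1e-9) {
    X <- .denseMatrix(X)
    m <- nrow(X); n <- ncol(X)
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be >= 1")
    if (k > min(m, n))
        stop("'k' (", k, ") exceeds min(dim(X)) = ", min(m, n))
    if (min(X) < 0) stop("'X' must be non-negative")
    seed <- .checkSeed(seed)

    set.seed(seed)
    scale0 <- sqrt(mean(X) / k)
    if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1e-3
    W <- matrix(stats::runif(m * k), m, k) * scale0
    H <- matrix(stats::runif(k * n), k, n) * scale0

    normX2 <- sum(X^2)
    errPrev <- Inf
    eps <- 1e-12
    for (iter in seq_len(maxIter)) {
        # update W columns
        HHt <- tcrossprod(H)               # k x k
        XHt <- X %*% t(H)                  # m x k
        for (j in seq_len(k)) {
            num <- XHt[, j] - W %*% HHt[, j] + W[, j] * HHt[j, j]
            W[, j] <- pmax(as.numeric(num) / max(HHt[j, j], eps), 0)
        }
        # update H rows
        WtW <- crossprod(W)                # k x k
        WtX <- crossprod(W, X)             # k x n
        for (j in seq_len(k)) {
            num <- WtX[j, ] - WtW[j, ] %*% H + WtW[j, j] * H[j, ]
            H[j, ] <- pmax(as.numeric(num) / max(WtW[j, j], eps), 0)
        }
        err <- normX2 - 2 * sum(WtX * H) + sum(crossprod(W) * tcrossprod(H))
        if (is.finite(errPrev) &&
            abs(errPrev - err) <= tol * max(errPrev, eps)) break
        errPrev <- err
    }
    dimnames(W) <- list(rownames(X), NULL)
    dimnames(H) <- list(NULL, colnames(X))
    list(W = W, H = H)
}
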