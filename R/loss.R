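# Objective, gradients and closed-form step sizes of the core model.
#
# The objective couples an NMF reconstruction to a similarity-smoothed
# view of the data:
#   F(W, H, Z) = ||X (Z o R) - W H||_F^2 + lambda ||Z - H'H||_F^2
#                + gamma1 ||W||_F^2 + gamma2 ||H||_F^2
# with X (m peaks x n cells) fixed, R a fixed binary mask, and
# W, H, Z >= 0. "o" is the Hadamard product.

#' Enhancement model objective
#'
#' Evaluates the coupled NMF / similarity objective either in its
#' Frobenius-norm form or in the algebraically equivalent trace form used
#' to derive the gradients. The two agree to floating-point accuracy;
#' both are exposed so the equivalence can be checked.
#'
#' @param X peak-by-cell matrix (dense or sparse; coerced dense).
#' @param W m x k projection matrix.
#' @param H k x n cell embedding.
#' @param Z n x n similarity matrix (columns need not sum to 1 mid-fit).
#' @param R n x n binary mask.
#' @param lambda,gamma1,gamma2 objective weights.
#' @param form `"norm"` (default) or `"trace"`.
#' @return non-negative scalar value of the objective.
#' @examples
#' X <- matrix(runif(30), 6, 5); Z <- diag(5); R <- matrix(1, 5, 5)
#' f <- runNMF(X, 2, seed = 1)
#' enhanceLoss(X, f$W, f$H, Z, R, lambda = 1, gamma1 = 0, gamma2 = 0)
#' @export
enhanceLoss <- function(X, W, H, Z, R, lambda = 1e6, gamma1 = 1,
                        gamma2 = 1, form = c("norm", "trace")) {
    form <- match.arg(form)
    X <- .denseMatrix(X)
    ZR <- Z * R
    if (form == "norm") {
        sum((X %*% ZR - W %*% H)^2) +
            lambda * sum((Z - crossprod(H))^2) +
            gamma1 * sum(W^2) + gamma2 * sum(H^2)
    } else {
        XZR <- X %*% ZR
        HtH <- crossprod(H)
        sum(XZR * XZR) - 2 * sum(crossprod(W, XZR) * H) +
            sum(crossprod(W) * tcrossprod(H)) +
            lambda * (sum(Z * Z) - 2 * sum(HtH * t(Z)) + sum(HtH * HtH)) +
            gamma1 * sum(W * W) + gamma2 * sum(H * H)
    }
}

#' Gradients of the enhancement objective
#'
#' Partial derivatives of the objective with respect to the projection
#' matrix, the cell embedding and the similarity matrix. The similarity
#' gradient carries the Hadamard mask on its data terms.
#'
#' @inheritParams enhanceLoss
#' @return list with components `W` (m x k), `H` (k x n) and `Z`
#'   (n x n).
#' @export
enhanceGradients <- function(X, W, H, Z, R, lambda = 1e6, gamma1 = 1,
                             gamma2 = 1) {
    X <- .denseMatrix(X)
    ZR <- Z * R
    XZR <- X %*% ZR
    HtH <- crossprod(H)
    dW <- -2 * XZR %*% t(H) + 2 * W %*% tcrossprod(H) + 2 * gamma1 * W
    dH <- -2 * crossprod(W, XZR) + 2 * crossprod(W) %*% H -
        2 * lambda * H %*% (Z + t(Z)) + 4 * lambda * tcrossprod(H) %*% H +
        2 * gamma2 * H
    dZ <- 2 * crossprod(X, XZR) * R - 2 * crossprod(X, W %*% H) * R +
        2 * lambda * Z - 2 * lambda * HtH
    list(W = dW, H = dH, Z = dZ)
}

#' Closed-form step size for the projection matrix
#'
#' Along a search direction `D1`, `F(W - delta * D1, H, Z)` is an exact
#' quadratic in `delta`; the minimizer has a closed form. The `gamma1`
#' ridge contributes a `delta`-dependent term that is included here so
#' the returned step is the exact 1-D minimizer of the full objective
#' (for `gamma1 = 0` this coincides with the data-term-only formula).
#'
#' @inheritParams enhanceLoss
#' @param D1 search direction (typically the gradient w.r.t. `W`).
#' @return the scalar minimizer; may be negative for an ascent
#'   direction, in which case the fit skips the update.
#' @export
optimalStepW <- function(X, W, H, Z, R, D1, gamma1 = 1) {
    X <- .denseMatrix(X)
    ZR <- Z * R
    XZRHt <- X %*% (ZR %*% t(H))
    HHt <- tcrossprod(H)
    num <- sum(D1 * (W %*% HHt)) - sum(D1 * XZRHt) + gamma1 * sum(D1 * W)
    den <- sum(crossprod(D1) * HHt) + gamma1 * sum(D1 * D1)
    if (den <= 1e-300)
        stop("degenerate direction: zero curvature along D1")
    num / den
}

#' Closed-form step size for the similarity matrix
#'
#' Along `D2`, `F(W, H, Z - delta * D2)` is quadratic in `delta` (the
#' similarity matrix appears in the masked data term and the consistency
#' term); the exact minimizer is returned.
#'
#' @inheritParams enhanceLoss
#' @param D2 search direction (typically the gradient w.r.t. `Z`).
#' @return the scalar minimizer; may be negative for an ascent
#'   direction, in which case the fit skips the update.
#' @export
optimalStepZ <- function(X, W, H, Z, R, D2, lambda = 1e6) {
    X <- .denseMatrix(X)
    ZR <- Z * R
    DR <- D2 * R
    XZR <- X %*% ZR
    XDR <- X %*% DR
    HtH <- crossprod(H)
    num <- sum(XDR * (XZR - W %*% H)) + lambda * sum(D2 * (Z - HtH))
    den <- sum(XDR * XDR) + lambda * sum(D2 * D2)
    if (den <= 1e-300)
        stop("degenerate direction: zero curvature along D2")
    num / den
}

#' Backtracked projected update of the cell embedding
#'
#' The embedding enters the objective at fourth order through the
#' consistency term, so no closed-form step exists. Starting from
#' `delta3Init` the step is halved until the projected update
#' `max(H - delta * D3, 0)` decreases the objective; if no step above
#' 1e-10 does, `H` is returned unchanged (a legal no-op).
#'
#' @inheritParams enhanceLoss
#' @param D3 search direction (typically the gradient w.r.t. `H`).
#' @param delta3Init initial step size (default 0.2).
#' @return the updated (or unchanged) non-negative embedding.
#' @export
updateH <- function(X, W, H, Z, R, D3, lambda = 1e6, gamma2 = 1,
                    gamma1 = 1, delta3Init = 0.2) {
    X <- .denseMatrix(X)
    f0 <- enhanceLoss(X, W, H, Z, R, lambda, gamma1, gamma2)
    delta <- delta3Init
    while (delta >= 1e-10) {
        Hn <- pmax(H - delta * D3, 0)
        if (enhanceLoss(X, W, Hn, Z, R, lambda, gamma1, gamma2) < f0)
            return(Hn)
        delta <- delta / 2
    }
    H
}

#' Reference-model objective (block and masked forms)
#'
#' Objective of the reference-anchored variant: the projection matrix is
#' the concatenation `[W1, W2]` of a reference-anchored block and a free
#' block, with an extra penalty `alpha ||P - W1||_F^2` tying the anchored
#' block to the reference basis `P`. The `"block"` form evaluates the
#' concatenation directly; the `"masked"` form realizes the same
#' objective through full-size Hadamard masks `M` (1 on the k1 anchored
#' columns) and `N = 1 - M`, with `W1` and `W2` zero-padded to m x k.
#' The two forms are algebraically identical.
#'
#' @inheritParams enhanceLoss
#' @param W1 m x k1 anchored block (k1 may be 0).
#' @param W2 m x k2 free block.
#' @param alpha anchoring weight.
#' @param P m x k1 reference basis.
#' @param form `"block"` (default) or `"masked"`.
#' @return non-negative scalar value of the objective.
#' @export
enhanceLossRef <- function(X, W1, W2, H, Z, R, lambda = 1e6, gamma1 = 1,
                           gamma2 = 1, alpha = 1, P = NULL,
                           form = c("block", "masked")) {
    form <- match.arg(form)
    X <- .denseMatrix(X)
    k1 <- ncol(W1); k2 <- ncol(W2); k <- k1 + k2
    if (form == "block") {
        Wm <- cbind(W1, W2)
        base <- enhanceLoss(X, Wm, H, Z, R, lambda, gamma1, gamma2)
        if (k1 > 0L) base + alpha * sum((P - W1)^2) else base
    } else {
        m <- nrow(X)
        M <- cbind(matrix(1, m, k1), matrix(0, m, k2))
        N <- 1 - M
        W1p <- cbind(W1, matrix(0, m, k2))
        W2p <- cbind(matrix(0, m, k1), W2)
        Wm <- M * W1p + N * W2p
        base <- enhanceLoss(X, Wm, H, Z, R, lambda, gamma1, gamma2)
        if (k1 > 0L) {
            Pp <- cbind(P, matrix(0, m, k2))
            base + alpha * sum((Pp - M * W1p)^2)
        } else base
    }
}

#' Gradients of the reference-model objective
#'
#' Derived from the masked trace form of the objective: the data and
#' ridge terms differentiate exactly as in the core model with
#' `Wm = [W1, W2]`, restricted to each block's columns, and the anchoring
#' penalty adds `2 alpha (W1 - P)` to the `W1` block.
#'
#' @inheritParams enhanceLossRef
#' @return list with components `W1`, `W2`, `H`, `Z`.
#' @export
enhanceGradientsRef <- function(X, W1, W2, H, Z, R, lambda = 1e6,
                                gamma1 = 1, gamma2 = 1, alpha = 1,
                                P = NULL) {
    Wm <- cbind(W1, W2)
    g <- enhanceGradients(X, Wm, H, Z, R, lambda, gamma1, gamma2)
    k1 <- ncol(W1)
    dW1 <- g$W[, seq_len(k1), drop = FALSE]
    if (k1 > 0L) dW1 <- dW1 + 2 * alpha * (W1 - P)
    dW2 <- g$W[, -seq_len(k1), drop = FALSE]
    if (k1 == 0L) dW2 <- g$W
    list(W1 = dW1, W2 = dW2, H = g$H, Z = g$Z)
}
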