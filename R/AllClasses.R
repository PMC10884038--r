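#' @import methods
#' @importFrom stats runif rbinom rlnorm prcomp cor sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' Parameters for the similarity-regularized NMF enhancement model
#'
#' `EnhanceParams` bundles every tunable of the core model: the latent
#' dimension `k`, the similarity-consistency weight `lambda`, the two ridge
#' regularization weights `gamma1` (projection matrix) and `gamma2` (cell
#' embedding), the Bernoulli success probability `maskP` of the random
#' binary mask applied to the similarity matrix, the relative-loss stopping
#' threshold `tol`, the iteration cap `maxIter`, the initial backtracking
#' step `delta3Init` for the embedding update, and the random `seed`.
#'
#' @slot k integer(1), latent dimension (>= 2).
#' @slot lambda numeric(1), weight of the similarity-consistency term.
#' @slot gamma1,gamma2 numeric(1), ridge weights on W and H.
#' @slot maskP numeric(1) in (0, 1], Bernoulli probability of the mask.
#' @slot tol numeric(1) > 0, relative change of the loss below which the
#'   fit is declared converged.
#' @slot maxIter integer(1), iteration cap.
#' @slot delta3Init numeric(1), initial step size for the embedding update.
#' @slot seed integer(1), base random seed (keep below 2^31 - 8; small
#'   offsets are derived from it for the factor initialization and mask).
#' @slot stopMode character(1), "relative" or "absolute" change of the loss.
#'
#' @seealso [enhanceParams()] for the user-facing constructor.
#' @export
setClass("EnhanceParams",
    representation(
        k = "integer", lambda = "numeric",
        gamma1 = "numeric", gamma2 = "numeric",
        maskP = "numeric", tol = "numeric", maxIter = "integer",
        delta3Init = "numeric", seed = "integer", stopMode = "character"
    ),
    prototype(
        k = 2L, lambda = 1e6, gamma1 = 1, gamma2 = 1, maskP = 0.8,
        tol = 1e-6, maxIter = 100L, delta3Init = 0.2, seed = 1L,
        stopMode = "relative"
    )
)

setValidity("EnhanceParams", function(object) {
    msg <- character()
    if (length(object@k) != 1L || object@k < 2L)
        msg <- c(msg, "'k' must be a single integer >= 2")
    if (object@lambda < 0 || object@gamma1 < 0 || object@gamma2 < 0)
        msg <- c(msg, "'lambda', 'gamma1' and 'gamma2' must be >= 0")
    if (object@maskP <= 0 || object@maskP > 1)
        msg <- c(msg, "'maskP' must lie in (0, 1]")
    if (object@tol <= 0)
        msg <- c(msg, "'tol' must be > 0")
    if (object@maxIter < 1L)
        msg <- c(msg, "'maxIter' must be >= 1")
    if (object@delta3Init <= 0)
        msg <- c(msg, "'delta3Init' must be > 0")
    if (!object@stopMode %in% c("relative", "absolute"))
        msg <- c(msg, "'stopMode' must be \"relative\" or \"absolute\"")
    if (length(msg)) msg else TRUE
})

#' Parameters for the reference-anchored model
#'
#' Extends [EnhanceParams-class] with the split of the projection matrix
#' into `k1` reference-anchored components and `k2 = k - k1` free
#' components, and the anchoring weight `alpha` that penalizes deviation
#' of the anchored block from the reference basis.
#'
#' @slot k1 integer(1), number of reference-anchored components
#'   (0 <= k1 <= k - 1; `k1 = 0` disables the reference block entirely and
#'   reduces the model to the core fit).
#' @slot alpha numeric(1) >= 0, anchoring weight.
#'
#' @seealso [refEnhanceParams()]
#' @export
setClass("RefEnhanceParams", contains = "EnhanceParams",
    representation(k1 = "integer", alpha = "numeric"),
    prototype(k1 = 1L, alpha = 1)
)

setValidity("RefEnhanceParams", function(object) {
    msg <- character()
    if (object@k1 < 0L || object@k1 >= object@k)
        msg <- c(msg, "'k1' must satisfy 0 <= k1 <= k - 1")
    if (object@alpha < 0)
        msg <- c(msg, "'alpha' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Fitted enhancement model
#'
#' The result of [fitEnhance()] or [fitEnhanceRef()]: the optimized
#' cell-to-cell similarity matrix (columns renormalized to sum to 1), the
#' non-negative projection matrix and cell embedding, the per-iteration
#' loss trace, and convergence information. For a reference fit, `k1`
#' components of the projection matrix are anchored to the reference basis
#' stored in `referenceBasis`.
#'
#' @slot W m x k non-negative projection matrix (peaks x components);
#'   row names are peak identifiers.
#' @slot H k x n non-negative cell embedding; column names are barcodes.
#' @slot Z n x n non-negative similarity matrix, each column summing to 1.
#' @slot lossTrace numeric, value of the objective after each iteration
#'   (element 1 is the value at initialization).
#' @slot nIter integer(1), iterations performed.
#' @slot converged logical(1).
#' @slot params the [EnhanceParams-class] (or subclass) used.
#' @slot referenceBasis m x k1 reference basis P (a 0-column matrix for
#'   core fits).
#'
#' @seealso [similarityMatrix()], [projectionMatrix()], [cellEmbedding()],
#'   [lossTrace()], [enhanceMatrix()]
#' @export
setClass("EnhanceFit",
    representation(
        W = "matrix", H = "matrix", Z = "matrix",
        lossTrace = "numeric", nIter = "integer", converged = "logical",
        params = "EnhanceParams", referenceBasis = "matrix"
    )
)

setValidity("EnhanceFit", function(object) {
    msg <- character()
    if (ncol(object@W) != nrow(object@H))
        msg <- c(msg, "ncol(W) must equal nrow(H)")
    if (nrow(object@Z) != ncol(object@Z) ||
        nrow(object@Z) != ncol(object@H))
        msg <- c(msg, "Z must be n x n with n = ncol(H)")
    if (min(object@W) < 0 || min(object@H) < 0 || min(object@Z) < 0)
        msg <- c(msg, "W, H and Z must be non-negative")
    if (object@nIter > object@params@maxIter)
        msg <- c(msg, "nIter exceeds maxIter")
    if (length(msg)) msg else TRUE
})

#' @describeIn EnhanceParams-class constructor.
#'
#' @param k latent dimension (number of factor components), integer >= 2.
#' @param lambda similarity-consistency weight; the published default is
#'   1e6.
#' @param gamma1,gamma2 ridge regularization weights on the projection
#'   matrix and the cell embedding.
#' @param maskP Bernoulli probability of the random binary mask.
#' @param tol stopping threshold on the (relative) change of the loss.
#' @param maxIter iteration cap.
#' @param delta3Init initial backtracking step for the embedding update.
#' @param seed base random seed (integer below 2^31 - 8).
#' @param stopMode interpret `tol` as a "relative" (default) or
#'   "absolute" change of the loss between consecutive iterations.
#' @return An `EnhanceParams` object.
#' @examples
#' enhanceParams(k = 5)
#' @export
enhanceParams <- function(k, lambda = 1e6, gamma1 = 1, gamma2 = 1,
                          maskP = 0.8, tol = 1e-6, maxIter = 100L,
                          delta3Init = 0.2, seed = 1L,
                          stopMode = c("relative", "absolute")) {
    new("EnhanceParams", k = as.integer(k), lambda = as.numeric(lambda),
        gamma1 = as.numeric(gamma1), gamma2 = as.numeric(gamma2),
        maskP = as.numeric(maskP), tol = as.numeric(tol),
        maxIter = as.integer(maxIter), delta3Init = as.numeric(delta3Init),
        seed = as.integer(seed), stopMode = match.arg(stopMode))
}

#' @describeIn RefEnhanceParams-class constructor.
#'
#' @param k total latent dimension (`k = k1 + k2`).
#' @param k1 number of reference-anchored components; `k1 = 0` yields the
#'   core model (the reference is ignored).
#' @param alpha anchoring weight tying the anchored block to the
#'   reference basis.
#' @param ... further arguments passed to [enhanceParams()].
#' @return A `RefEnhanceParams` object.
#' @examples
#' refEnhanceParams(k = 6, k1 = 3, alpha = 1)
#' @export
refEnhanceParams <- function(k, k1 = 1L, alpha = 1, ...) {
    base <- enhanceParams(k = k, ...)
    new("RefEnhanceParams", base, k1 = as.integer(k1),
        alpha = as.numeric(alpha))
}

#' @export
setMethod("show", "EnhanceParams", function(object) {
    cat("EnhanceParams: k =", object@k,
        "lambda =", format(object@lambda),
        "gamma1 =", object@gamma1, "gamma2 =", object@gamma2, "\n",
        " maskP =", object@maskP, "tol =", format(object@tol),
        "maxIter =", object@maxIter, "seed =", object@seed, "\n")
    if (is(object, "RefEnhanceParams"))
        cat(" reference block: k1 =", object@k1,
            "k2 =", object@k - object@k1, "alpha =", object@alpha, "\n")
})

#' @export
setMethod("show", "EnhanceFit", function(object) {
    cat("EnhanceFit:", nrow(object@W), "peaks x", ncol(object@H),
        "cells, k =", ncol(object@W), "\n")
    if (ncol(object@referenceBasis) > 0L)
        cat("  reference-anchored components:",
            ncol(object@referenceBasis), "\n")
    cat("  iterations:", object@nIter,
        if (object@converged) "(converged)" else "(not converged)", "\n")
    cat("  final loss:", format(object@lossTrace[length(object@lossTrace)]),
        "\n")
})
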