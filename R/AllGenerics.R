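#' Accessors for fitted enhancement models
#'
#' Extract the components of an [EnhanceFit-class]: the column-stochastic
#' cell-to-cell similarity matrix, the non-negative projection matrix
#' (peaks x components), the cell embedding (components x cells), the
#' per-iteration loss trace, and convergence information.
#'
#' @param object an `EnhanceFit`.
#' @return `similarityMatrix`: an n x n matrix whose columns sum to 1;
#'   `projectionMatrix`: an m x k matrix; `cellEmbedding`: a k x n matrix;
#'   `lossTrace`: a numeric vector (element 1 is the loss at
#'   initialization); `nIterations`: an integer; `isConverged`: a logical;
#'   `referenceBasis`: the m x k1 reference basis (0 columns for core
#'   fits); `modelParams`: the parameter object used for the fit.
#'
#' @examples
#' sim <- simulateAccessibility(nClusters = 2, cellsPerCluster = 15,
#'                              markerPeaksPerCluster = 40, seed = 1)
#' x <- tfidfTransform(filterPeaks(sim))
#' fit <- fitEnhance(x, enhanceParams(k = 2, maxIter = 3, seed = 1))
#' dim(similarityMatrix(fit))
#' lossTrace(fit)
#' @name EnhanceFit-accessors
NULL

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("similarityMatrix", function(object)
    standardGeneric("similarityMatrix"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("projectionMatrix", function(object)
    standardGeneric("projectionMatrix"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("cellEmbedding", function(object)
    standardGeneric("cellEmbedding"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("referenceBasis", function(object)
    standardGeneric("referenceBasis"))

#' @rdname EnhanceFit-accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname EnhanceFit-accessors
#' @export
setMethod("similarityMatrix", "EnhanceFit", function(object) object@Z)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("projectionMatrix", "EnhanceFit", function(object) object@W)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("cellEmbedding", "EnhanceFit", function(object) object@H)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("lossTrace", "EnhanceFit", function(object) object@lossTrace)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("nIterations", "EnhanceFit", function(object) object@nIter)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("isConverged", "EnhanceFit", function(object) object@converged)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("referenceBasis", "EnhanceFit", function(object)
    object@referenceBasis)

#' @rdname EnhanceFit-accessors
#' @export
setMethod("modelParams", "EnhanceFit", function(object) object@params)

#' @rdname filterPeaks
#' @export
setGeneric("filterPeaks", function(x, minCellFraction = 0.01, ...)
    standardGeneric("filterPeaks"))

#' @rdname tfidfTransform
#' @export
setGeneric("tfidfTransform", function(x, idfOnBinarized = TRUE, ...)
    standardGeneric("tfidfTransform"))
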