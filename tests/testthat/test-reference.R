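test_that("reference NMF spans indicator profiles and is deterministic", {
    # orthogonal indicator profiles: s = k1 blocks
    ref <- kronecker(diag(3), matrix(5, 4, 1))
    P <- nmfReference(ref, 3, seed = 1)
    H <- runNMF(ref, 3, seed = 1)$H
    expect_lt(sqrt(sum((ref - P %*% H)^2)), 1e-6 * sqrt(sum(ref^2)))
    # rank-1: basis proportional to the single profile
    one <- matrix(c(1, 2, 3, 4), 4, 1)
    P1 <- nmfReference(one, 1, seed = 2)
    expect_lt(sd(P1 / one), 1e-6 * mean(P1 / one))
    expect_identical(nmfReference(ref, 2, seed = 3),
                     nmfReference(ref, 2, seed = 3))
    expect_error(nmfReference(ref, 4, seed = 1), "samples")
})

test_that("masked form and block form of the reference objective agree", {
    for (seed in 1:4) {
        set.seed(seed)
        m <- 7; n <- 5; k1 <- 2; k2 <- 2
        X <- matrix(runif(m * n), m, n)
        W1 <- matrix(runif(m * k1), m, k1)
        W2 <- matrix(runif(m * k2), m, k2)
        H <- matrix(runif((k1 + k2) * n), k1 + k2, n)
        Z <- matrix(runif(n * n), n, n)
        R <- matrix(rbinom(n * n, 1, 0.8), n, n)
        P <- matrix(runif(m * k1), m, k1)
        a <- enhanceLossRef(X, W1, W2, H, Z, R, 3, 0.5, 0.7, 1.5, P,
                            form = "block")
        b <- enhanceLossRef(X, W1, W2, H, Z, R, 3, 0.5, 0.7, 1.5, P,
                            form = "masked")
        expect_equal(a, b, tolerance = 1e-12)
    }
})

test_that("reference-model gradients match finite differences", {
    set.seed(11)
    m <- 6; n <- 5; k1 <- 1; k2 <- 1
    X <- matrix(runif(m * n), m, n)
    W1 <- matrix(runif(m * k1), m, k1)
    W2 <- matrix(runif(m * k2), m, k2)
    H <- matrix(runif((k1 + k2) * n), k1 + k2, n)
    Z <- matrix(runif(n * n), n, n)
    R <- matrix(rbinom(n * n, 1, 0.8), n, n)
    P <- matrix(runif(m * k1), m, k1)
    g <- enhanceGradientsRef(X, W1, W2, H, Z, R, 2, 0.5, 0.7, 1.5, P)
    fd <- function(M, name) {
        out <- M
        h <- 1e-6
        for (i in seq_along(M)) {
            pert <- function(v) {
                a <- list(W1 = W1, W2 = W2, H = H, Z = Z)
                a[[name]][i] <- v
                enhanceLossRef(X, a$W1, a$W2, a$H, a$Z, R, 2, 0.5, 0.7,
                               1.5, P)
            }
            out[i] <- (pert(M[i] + h) - pert(M[i] - h)) / (2 * h)
        }
        out
    }
    for (nm in c("W1", "W2", "H", "Z"))
        expect_lt(max(abs(g[[nm]] -
                          fd(list(W1 = W1, W2 = W2, H = H, Z = Z)[[nm]],
                             nm))), 1e-4)
})

test_that("alpha = 0 with an empty anchored block reproduces the core fit", {
    sim <- smallSim(seed = 31)
    x <- tfidfTransform(filterPeaks(sim))
    core <- fitEnhance(x, enhanceParams(k = 3, maxIter = 12, seed = 4))
    red <- suppressMessages(fitEnhanceRef(
        x, ref = NULL,
        refEnhanceParams(k = 3, k1 = 0, alpha = 0, maxIter = 12, seed = 4)))
    expect_identical(lossTrace(core), lossTrace(red))
    expect_identical(projectionMatrix(core), projectionMatrix(red))
    expect_identical(similarityMatrix(core), similarityMatrix(red))
})

test_that("stronger anchoring pulls the anchored block toward the basis", {
    sim <- smallSim(nClusters = 3, cells = 12, markers = 30, seed = 32)
    x <- tfidfTransform(filterPeaks(sim))
    ref <- buildPseudobulk(x, SummarizedExperiment::colData(x)$cell_type)
    gaps <- vapply(c(1, 10, 100), function(a) {
        fit <- fitEnhanceRef(x, ref,
            refEnhanceParams(k = 4, k1 = 2, alpha = a, maxIter = 20,
                             seed = 5))
        W1 <- projectionMatrix(fit)[, 1:2]
        sqrt(sum((referenceBasis(fit) - W1)^2))
    }, numeric(1))
    expect_true(all(diff(gaps) < 0))
})

test_that("bulk scaling is depth-invariant and matches hand division", {
    bulk <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60),
                  s3 = c(5, 0, 5))
    out <- buildReferenceFromBulk(bulk, c(100, 200, 50))
    expect_equal(out[, "s1"], out[, "s2"])  # same profile, double depth
    expect_equal(unname(out[, "s3"]), c(5, 0, 5) / (50 / 1e6))
    expect_equal(unname(out[, "s1"]), c(10, 20, 30) / (100 / 1e6))
    expect_error(buildReferenceFromBulk(bulk, c(100, 0, 50)), "zero")
})

test_that("pseudo-bulk aggregation sums counts per label", {
    m <- matrix(c(1, 0, 2, 1, 0, 3, 4, 0), 2, 4,
                dimnames = list(c("p1", "p2"), paste0("c", 1:4)))
    pb <- buildPseudobulk(m, c("A", "B", "A", "B"))
    expect_equal(unname(pb[, "A"]), c(1 + 0, 0 + 3))
    expect_equal(unname(pb[, "B"]), c(2 + 4, 1 + 0))
    # one cell per label: a column permutation of the input
    pb1 <- buildPseudobulk(m, c("w", "x", "y", "z"))
    expect_equal(unname(pb1), unname(m), ignore_attr = TRUE)
    # single label: row sums
    pb2 <- buildPseudobulk(m, rep("all", 4))
    expect_equal(unname(pb2[, 1]), unname(rowSums(m)))
    expect_warning(
        buildPseudobulk(m, factor(c("A", "B", "A", "B"),
                                  levels = c("A", "B", "C"))),
        "empty")
})

test_that("self-reference recovers planted clusters deterministically", {
    sim <- smallSim(nClusters = 2, cells = 20, markers = 60, seed = 33,
                    backgroundOpenProb = 0.02)
    x <- tfidfTransform(filterPeaks(sim))
    # (50 principal components exceed this toy's dimensionality; the
    # clamp warning is expected)
    ref <- suppressWarnings(buildSelfReference(x, resolution = 1, seed = 3))
    expect_identical(ref, suppressWarnings(
        buildSelfReference(x, resolution = 1, seed = 3)))
    if (ncol(ref) == 2L) {
        truePb <- buildPseudobulk(x, SummarizedExperiment::colData(x)$cell_type)
        # same two columns up to order
        expect_equal(sort(colSums(ref)), sort(colSums(truePb)))
    }
    # degenerate resolution: one community, equals single-label pseudo-bulk
    ref0 <- suppressWarnings(buildSelfReference(x, resolution = 1e-6,
                                                seed = 3))
    expect_identical(ncol(ref0), 1L)
    expect_equal(unname(ref0[, 1]),
                 unname(buildPseudobulk(x, rep("a", ncol(x)))[, 1]))
})

test_that("peak alignment is enforced and repairable", {
    sim <- smallSim(seed = 34)
    x <- tfidfTransform(filterPeaks(sim))
    ref <- buildPseudobulk(x, SummarizedExperiment::colData(x)$cell_type)
    refBad <- ref[-1, , drop = FALSE]
    expect_error(fitEnhanceRef(x, refBad,
        refEnhanceParams(k = 3, k1 = 1, maxIter = 2, seed = 1)),
        "align")
    al <- suppressMessages(alignPeakSets(x, refBad))
    expect_identical(nrow(al$x), nrow(al$ref))
    fit <- fitEnhanceRef(al$x, al$ref,
        refEnhanceParams(k = 3, k1 = 2, maxIter = 3, seed = 1))
    expect_s4_class(fit, "EnhanceFit")
    expect_identical(ncol(referenceBasis(fit)), 2L)
})
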