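suppressPackageStartupMessages({
    library(SingleCellExperiment)
    library(Matrix)
})

# Small planted-cluster dataset used across tests.
smallSim <- function(nClusters = 3, cells = 15, markers = 40, seed = 1,
                     ...) {
    simulateAccessibility(nClusters = nClusters, cellsPerCluster = cells,
                          markerPeaksPerCluster = markers, seed = seed,
                          ...)
}

# Random dense instance of the optimization problem.
randomInstance <- function(m = 6, n = 5, k = 2, seed = 1, maskP = 0.8) {
    set.seed(seed)
    list(X = matrix(runif(m * n), m, n),
         W = matrix(runif(m * k), m, k),
         H = matrix(runif(k * n), k, n),
         Z = matrix(runif(n * n), n, n),
         R = matrix(rbinom(n * n, 1, maskP), n, n))
}

# Central finite-difference gradient of the core objective w.r.t. one
# factor ("W", "H" or "Z"); the independent oracle for gradient tests.
numericalGradient <- function(inst, wrt, lambda, gamma1, gamma2,
                              h = 1e-6) {
    M <- inst[[wrt]]
    out <- M
    for (i in seq_along(M)) {
        up <- M; up[i] <- up[i] + h
        dn <- M; dn[i] <- dn[i] - h
        ai <- inst; ai[[wrt]] <- up
        bi <- inst; bi[[wrt]] <- dn
        fa <- enhanceLoss(ai$X, ai$W, ai$H, ai$Z, ai$R, lambda, gamma1,
                          gamma2)
        fb <- enhanceLoss(bi$X, bi$W, bi$H, bi$Z, bi$R, lambda, gamma1,
                          gamma2)
        out[i] <- (fa - fb) / (2 * h)
    }
    out
}
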