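test_that("PCA scores behave like centered PCA", {
    set.seed(40)
    X <- matrix(runif(30 * 8), 30, 8)
    X[, 5] <- X[, 2]                       # duplicated cell
    sc <- pcaReduce(X, nComponents = 5)
    expect_equal(sc[5, ], sc[2, ])
    vars <- apply(sc, 2, var)
    expect_true(all(diff(vars) <= 1e-12))
    # exact low-rank reconstruction
    L <- matrix(runif(30 * 2), 30, 2) %*% matrix(runif(2 * 8), 2, 8)
    p <- prcomp(t(L), rank. = 2)
    rec <- p$x %*% t(p$rotation) + matrix(p$center, 8, 30, byrow = TRUE)
    expect_equal(rec, unname(t(L)), tolerance = 1e-8)
    expect_warning(pcaReduce(X, nComponents = 50), "clamped")
})

test_that("binary-searched Louvain recovers planted blobs", {
    set.seed(41)
    emb <- rbind(matrix(rnorm(30 * 2, 0), 30, 2),
                 matrix(rnorm(30 * 2, 10), 30, 2))
    lab <- louvainClusters(emb, targetK = 2, seed = 5)
    truth <- rep(1:2, each = 30)
    expect_identical(attr(lab, "nClusters"), 2L)
    expect_equal(clusteringMetrics(lab, truth)$ari, 1)
    expect_false(attr(lab, "mismatch"))
    expect_identical(as.integer(lab),
                     as.integer(louvainClusters(emb, targetK = 2, seed = 5)))
    # unreachable target flags a mismatch
    expect_warning(bad <- louvainClusters(emb, targetK = 60, maxProbes = 8,
                                          seed = 5), "could not reach")
    expect_true(attr(bad, "mismatch"))
})

test_that("agreement metrics match brute-force pair counting", {
    pred <- c(1, 1, 2, 2)
    truth <- c("a", "b", "b", "b")
    # pair counting oracle
    pairs <- t(combn(4, 2))
    sameP <- pred[pairs[, 1]] == pred[pairs[, 2]]
    sameT <- truth[pairs[, 1]] == truth[pairs[, 2]]
    tp <- sum(sameP & sameT); fp <- sum(sameP & !sameT)
    fn <- sum(!sameP & sameT); tn <- sum(!sameP & !sameT)
    fmiOracle <- tp / sqrt((tp + fp) * (tp + fn))
    nPairs <- nrow(pairs)
    sumP <- tp + fp; sumT <- tp + fn
    expIdx <- sumP * sumT / nPairs
    ariOracle <- (tp - expIdx) / ((sumP + sumT) / 2 - expIdx)
    got <- clusteringMetrics(pred, truth)
    expect_equal(got$fmi, fmiOracle)
    expect_equal(got$ari, ariOracle)

    # perfect agreement and label-renaming invariance
    perf <- clusteringMetrics(c(2, 2, 1, 1), c("x", "x", "y", "y"))
    expect_equal(perf$ari, 1); expect_equal(perf$ami, 1)
    expect_equal(perf$fmi, 1)
    ren <- clusteringMetrics(c(9, 9, 7, 7), c("x", "x", "y", "y"))
    expect_equal(ren, perf)
    expect_error(clusteringMetrics(1:3, 1:4), "equal length")
})

test_that("random labelings score at chance level", {
    set.seed(42)
    truth <- rep(1:2, each = 500)
    aris <- amis <- numeric(20)
    for (s in 1:20) {
        pred <- sample(truth)
        m <- clusteringMetrics(pred, truth)
        aris[s] <- m$ari; amis[s] <- m$ami
    }
    expect_lt(max(abs(aris)), 0.05)
    expect_lt(max(abs(amis)), 0.05)
})

test_that("Pearson silhouette matches brute-force arithmetic", {
    # two groups of mutually identical profiles, uncorrelated across
    set.seed(43)
    a <- rnorm(50); b <- rnorm(50)
    X <- cbind(a, a, b, b)
    sil <- silhouettePearson(X, c("g1", "g1", "g2", "g2"))
    expect_gt(sil, 0.9)

    # 4-cell hand instance against explicit a(i)/b(i) computation
    X2 <- matrix(runif(40), 10, 4)
    lab <- c("u", "u", "v", "v")
    d <- 1 - cor(X2)
    aW <- c(d[1, 2], d[2, 1], d[3, 4], d[4, 3])
    bW <- c(mean(d[1, 3:4]), mean(d[2, 3:4]),
            mean(d[3, 1:2]), mean(d[4, 1:2]))
    silOracle <- mean((bW - aW) / pmax(aW, bW))
    expect_equal(silhouettePearson(X2, lab), silOracle, tolerance = 1e-12)

    # shuffled labels never beat the true ones on separated groups
    X3 <- cbind(matrix(rnorm(200, 0), 50, 4) + a,
                matrix(rnorm(200, 0), 50, 4) + b)
    lab3 <- rep(c("p", "q"), each = 4)
    s0 <- silhouettePearson(X3, lab3)
    worse <- vapply(1:20, function(s) {
        set.seed(s)
        silhouettePearson(X3, sample(lab3))
    }, numeric(1))
    expect_true(all(worse <= s0 + 1e-12))

    # constant profile: distance 1 with a warning
    X4 <- cbind(rep(1, 10), runif(10), runif(10), runif(10))
    expect_warning(silhouettePearson(X4, c("a", "a", "b", "b")),
                   "constant")
})

test_that("AUCs match exhaustive threshold enumeration", {
    scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
    y <- c(1, 0, 1, 1, 0, 0)
    rec <- signalRecovery(matrix(scores, 6, 1), matrix(y, 6, 1),
                          "cellwise")
    # threshold-enumeration oracle
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- fpr <- prec <- rec2 <- numeric(length(th))
    for (i in seq_along(th)) {
        call <- scores >= th[i]
        tpr[i] <- sum(call & y == 1) / sum(y == 1)
        fpr[i] <- sum(call & y == 0) / sum(y == 0)
        prec[i] <- sum(call & y == 1) / sum(call)
    }
    # trapezoid over the (fpr, tpr) curve
    aurocOracle <- sum(diff(c(0, fpr)) *
                       (head(c(0, tpr), -1) + tpr) / 2)
    auprcOracle <- sum(diff(c(0, tpr)) * prec)
    expect_equal(rec$auroc[1], aurocOracle)
    expect_equal(rec$auprc[1], auprcOracle)

    # perfect scores
    perf <- signalRecovery(matrix(y, 6, 1), matrix(y, 6, 1), "cellwise")
    expect_equal(perf$auroc[1], 1)
    expect_equal(perf$auprc[1], 1)

    # invariance to strictly monotone transforms
    tr <- signalRecovery(matrix(exp(3 * scores), 6, 1), matrix(y, 6, 1),
                         "cellwise")
    expect_equal(tr$auroc[1], rec$auroc[1])
    expect_equal(tr$auprc[1], rec$auprc[1])
})

test_that("uninformative scores give chance-level auROC", {
    set.seed(44)
    vals <- vapply(1:20, function(s) {
        y <- rep(0:1, each = 500)
        signalRecovery(matrix(runif(1000), 1000, 1),
                       matrix(y, 1000, 1), "cellwise")$auroc[1]
    }, numeric(1))
    expect_lt(abs(mean(vals) - 0.5), 0.05)
})

test_that("single-class units are skipped and counted", {
    E <- matrix(runif(20), 5, 4)
    Tr <- cbind(c(1, 0, 1, 0, 1), rep(1, 5), c(0, 0, 1, 1, 0), rep(0, 5))
    rec <- signalRecovery(E, Tr, "cellwise")
    expect_identical(rec$nSkipped, 2L)
    expect_identical(which(is.na(rec$auprc)), c(2L, 4L))
    expect_error(signalRecovery(E, matrix(1, 5, 4), "cellwise"),
                 "single-class")
})

test_that("imbalance degree matches the normalized-entropy formula", {
    expect_equal(imbalanceDegree(rep(letters[1:4], each = 25)), 0)
    expect_equal(imbalanceDegree(rep("a", 100),
                                 typeInventory = c("a", "b")), 1)
    # C = 2, counts (3, 1)
    expect_equal(imbalanceDegree(c("a", "a", "a", "b")),
                 1 + (0.75 * log(0.75) + 0.25 * log(0.25)) / log(2),
                 tolerance = 1e-12)
    # strictly increasing as mass concentrates (majorization chain)
    chain <- list(c(4, 4, 4), c(6, 4, 2), c(8, 2, 2), c(10, 1, 1))
    vals <- vapply(chain, function(ct)
        imbalanceDegree(rep(c("x", "y", "z"), ct)), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_gte(min(vals), 0); expect_lte(max(vals), 1)
    expect_error(imbalanceDegree(rep("a", 5)), "inventory")
})

test_that("the evaluation report aggregates every metric", {
    sim <- smallSim(nClusters = 2, cells = 20, markers = 50, seed = 45)
    x <- tfidfTransform(filterPeaks(sim))
    truth <- as.matrix(assay(sim, "truth"))[rownames(x), ]
    rep <- evaluateEnhancement(x, colData(sim)$cell_type, truth = truth,
                               assay = "tfidf", nComponents = 10,
                               seed = 2)
    expect_true(all(c("ari", "ami", "fmi", "silhouette",
                      "meanCellwiseAuprc", "meanPeakwiseAuroc")
                    %in% names(rep)))
    expect_true(rep$ari >= -1 && rep$ari <= 1)
    expect_true(rep$meanCellwiseAuprc >= 0 && rep$meanCellwiseAuprc <= 1)
})
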