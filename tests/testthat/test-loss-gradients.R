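# Oracle checks of the objective, its gradients and the closed-form
# step sizes on small dense instances.

lam <- 2; g1 <- 0.5; g2 <- 0.7

test_that("norm form and trace form of the objective agree", {
    for (seed in 1:5) {
        inst <- randomInstance(6, 5, 2, seed = seed)
        a <- with(inst, enhanceLoss(X, W, H, Z, R, lam, g1, g2, "norm"))
        b <- with(inst, enhanceLoss(X, W, H, Z, R, lam, g1, g2, "trace"))
        expect_lt(abs(a - b) / a, 1e-8)
    }
})

test_that("vanishing and exact-fit limits of the objective", {
    inst <- randomInstance(6, 5, 2, seed = 2)
    # W = H = 0 and zero weights leave only the masked data term
    expect_equal(
        enhanceLoss(inst$X, 0 * inst$W, 0 * inst$H, inst$Z, inst$R,
                    0, 0, 0),
        sum((inst$X %*% (inst$Z * inst$R))^2))
    # exact fit: X = WH with row-orthonormal H, Z = H'H (idempotent),
    # R = 1 and no ridge -> both residual terms vanish
    H <- rbind(c(1, 1, 0, 0, 0) / sqrt(2), c(0, 0, 0, 1, 1) / sqrt(2))
    X <- inst$W %*% H
    Z <- crossprod(H)
    R1 <- matrix(1, 5, 5)
    expect_equal(enhanceLoss(X, inst$W, H, Z, R1, lam, 0, 0), 0)
})

test_that("analytic gradients match central finite differences", {
    for (seed in 1:3) {
        inst <- randomInstance(6, 5, 2, seed = seed)
        g <- with(inst, enhanceGradients(X, W, H, Z, R, lam, g1, g2))
        for (wrt in c("W", "H", "Z")) {
            fd <- numericalGradient(inst, wrt, lam, g1, g2)
            expect_lt(max(abs(g[[wrt]] - fd)), 1e-4)
        }
    }
})

test_that("gradient limits: W = 0 and the W-stationary point", {
    inst <- randomInstance(6, 5, 2, seed = 4)
    gz <- with(inst, enhanceGradients(X, 0 * W, H, Z, R, lam, g1, g2))
    expect_equal(gz$W,
                 with(inst, -2 * X %*% (Z * R) %*% t(H)))
    # W* = X(ZoR)H'(HH' + g1 I)^{-1} zeroes the W-gradient
    Wstar <- with(inst, X %*% (Z * R) %*% t(H) %*%
                      solve(tcrossprod(H) + g1 * diag(2)))
    gs <- with(inst, enhanceGradients(X, Wstar, H, Z, R, lam, g1, g2))
    expect_lt(max(abs(gs$W)), 1e-10)
})

test_that("closed-form W step is the grid-scan minimizer and descends", {
    inst <- randomInstance(6, 5, 2, seed = 5)
    D1 <- with(inst, enhanceGradients(X, W, H, Z, R, lam, g1, g2))$W
    d1 <- with(inst, optimalStepW(X, W, H, Z, R, D1, g1))
    grid <- seq(0, 2 * d1, length.out = 10001)
    fv <- vapply(grid, function(d)
        with(inst, enhanceLoss(X, W - d * D1, H, Z, R, lam, g1, g2)),
        numeric(1))
    expect_lt(abs(grid[which.min(fv)] - d1), diff(grid[1:2]) + 1e-12)
    f0 <- with(inst, enhanceLoss(X, W, H, Z, R, lam, g1, g2))
    f1 <- with(inst, enhanceLoss(X, W - d1 * D1, H, Z, R, lam, g1, g2))
    expect_lt(f1, f0)
    # quadratic structure: the vertex of a 3-point parabola fit equals d1
    ds <- c(0, d1 / 2, d1 * 1.5)
    fs <- vapply(ds, function(d)
        with(inst, enhanceLoss(X, W - d * D1, H, Z, R, lam, g1, g2)),
        numeric(1))
    co <- solve(cbind(1, ds, ds^2), fs)
    expect_equal(-co[2] / (2 * co[3]), d1, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_error(with(inst, optimalStepW(X, W, H, Z, R, 0 * D1, g1)),
                 "degenerate")
})

test_that("closed-form Z step matches grid scan, special case and sign", {
    inst <- randomInstance(6, 5, 2, seed = 6)
    D2 <- with(inst, enhanceGradients(X, W, H, Z, R, lam, g1, g2))$Z
    d2 <- with(inst, optimalStepZ(X, W, H, Z, R, D2, lam))
    grid <- seq(0, 2 * d2, length.out = 10001)
    fv <- vapply(grid, function(d)
        with(inst, enhanceLoss(X, W, H, Z - d * D2, R, lam, g1, g2)),
        numeric(1))
    expect_lt(abs(grid[which.min(fv)] - d2), diff(grid[1:2]) + 1e-12)

    # lambda = 0 reduces to the data-term minimizer derived independently
    D2b <- with(inst, enhanceGradients(X, W, H, Z, R, 0, g1, g2))$Z
    d2b <- with(inst, optimalStepZ(X, W, H, Z, R, D2b, 0))
    ref <- with(inst, {
        DR <- D2b * R
        XDR <- X %*% DR
        sum(XDR * (X %*% (Z * R) - W %*% H)) / sum(XDR^2)
    })
    expect_equal(d2b, ref, tolerance = 1e-12)

    # an ascent direction yields a negative optimal step
    expect_lt(with(inst, optimalStepZ(X, W, H, Z, R, -D2, lam)), 0)
    expect_error(with(inst, optimalStepZ(X, W, H, Z, R, 0 * D2, lam)),
                 "degenerate")
})

test_that("embedding update backtracks, clips and never increases loss", {
    inst <- randomInstance(6, 5, 2, seed = 7)
    D3 <- with(inst, enhanceGradients(X, W, H, Z, R, lam, g1, g2))$H
    # zero direction is a no-op
    expect_identical(with(inst, updateH(X, W, H, Z, R, 0 * D3, lam, g2, g1)),
                     inst$H)
    Hn <- with(inst, updateH(X, W, H, Z, R, D3, lam, g2, g1))
    expect_true(all(Hn >= 0))
    f0 <- with(inst, enhanceLoss(X, W, H, Z, R, lam, g1, g2))
    fn <- with(inst, enhanceLoss(X, W, Hn, Z, R, lam, g1, g2))
    expect_lte(fn, f0)
    # entries pushed negative are clipped exactly to zero
    big <- with(inst, updateH(X, W, H, Z, R, matrix(1e6, 2, 5) * sign(D3),
                              lam, g2, g1))
    expect_true(all(big >= 0))
})
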