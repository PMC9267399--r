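test_that("least-squares fit recovers known coefficients", {
    net <- unidirNet()        # A1 = [[0.9, 0], [0.5, 0.8]]
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 10,
                         samplingRate = 500, seed = 11)
    m <- fitMVAR(es, p = 1, i = 1)
    expect_lt(max(abs(coefArray(m)[, , 1] - coefArray(net)[, , 1])), 0.05)
    expect_equal(m@nSamples, 4999)

    # white noise: coefficients within 3 standard errors of zero
    wn <- makeGroundTruth(3, diagAR = 0)
    esw <- simulateEpochs(wn, nEpochs = 1, epochLength = 10,
                          samplingRate = 500, seed = 12)
    mw <- fitMVAR(esw, p = 1, i = 1)
    se <- 1 / sqrt(mw@nSamples)
    expect_lt(max(abs(coefArray(mw))), 3 * se)
})

test_that("fit agrees with an independent naive regression solve", {
    # oracle: explicit lagged design matrix + qr.solve, nothing shared with
    # the compiled path
    net <- order3Net()
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 0.4,
                         samplingRate = 500, seed = 13)
    X <- epochMatrix(es, 1)   # 3 x 200
    p <- 2
    Tn <- ncol(X); k <- nrow(X)
    Z <- NULL; Y <- t(X[, (p + 1):Tn])
    for (l in 1:p) Z <- cbind(Z, t(X[, (p + 1 - l):(Tn - l)]))
    Bref <- qr.solve(Z, Y)
    Aref <- array(0, c(k, k, p))
    for (l in 1:p) Aref[, , l] <- t(Bref[((l - 1) * k + 1):(l * k), ])
    m <- fitMVAR(X, p = p)
    expect_lt(max(abs(coefArray(m) - Aref)), 1e-8)
    Eref <- Y - Z %*% Bref
    Sref <- crossprod(Eref) / (nrow(Y) - p * k)
    expect_lt(max(abs(noiseCov(m) - Sref)), 1e-8)
})

test_that("degenerate fits fail loudly", {
    expect_error(fitMVAR(matrix(rnorm(19 * 10), 19), p = 5), "too short")
    X <- rbind(rnorm(300), rep(1, 300) * 0)
    rownames(X) <- c("good", "flat")
    expect_error(fitMVAR(X, p = 2), "flat")
})

test_that("coefficient error shrinks with sample size", {
    net <- unidirNet()
    A0 <- coefArray(net)[, , 1]
    rmse <- sapply(c(500, 2000, 8000), function(Tn) {
        errs <- sapply(1:20, function(r) {
            es <- simulateEpochs(net, nEpochs = 1, epochLength = Tn / 500,
                                 samplingRate = 500, seed = 5000 + r)
            sqrt(mean((coefArray(fitMVAR(es, 1, i = 1))[, , 1] - A0)^2))
        })
        median(errs)
    })
    expect_true(all(diff(rmse) < 0))
})

test_that("SBC prefers the true order and degrades for overfits", {
    net <- makeGroundTruth(2, couplingEdges(1, 2, 2, 0.4), diagAR = 0.5,
                           order = 2)
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 4,
                         samplingRate = 500, seed = 21)
    X <- epochMatrix(es, 1)
    # oracle: direct evaluation of the formula from an independent fit
    s2 <- sbcScore(X, 2, pMax = 8)
    s8 <- sbcScore(X, 8, pMax = 8)
    expect_lt(s2, s8)

    # white noise: smallest candidate wins in most runs
    wn <- makeGroundTruth(3, diagAR = 0)
    hits <- sapply(1:50, function(r) {
        e <- simulateEpochs(wn, nEpochs = 1, epochLength = 0.6,
                            samplingRate = 500, seed = 900 + r)
        X <- epochMatrix(e, 1)
        cand <- 1:5
        which.min(vapply(cand, function(p) sbcScore(X, p, pMax = 5), 0)) == 1
    })
    expect_gte(mean(hits), 0.8)
})

test_that("order selection takes the epoch-median SBC argmin", {
    net <- order3Net()
    es <- simulateEpochs(net, nEpochs = 20, epochLength = 2,
                         samplingRate = 500, seed = 31)
    sel <- selectOrder(es, 2, 8)
    expect_identical(sel$order, 3L)
    expect_identical(sel$order, as.integer(median(sel$perEpoch)))

    # singleton range: no search
    sel4 <- selectOrder(es, 4, 4)
    expect_identical(sel4$order, 4L)

    # identical epochs: the ensemble median is that epoch's argmin
    one <- es@epochs[, , 1, drop = FALSE]
    same <- new("EpochSet",
                epochs = array(rep(one, 5), dim = c(3, 1000, 5)),
                samplingRate = 500, channelNames = channelNames(es),
                epochLength = 2)
    sels <- selectOrder(same, 2, 8)
    expect_identical(sels$order, as.integer(sels$perEpoch[1]))
    expect_true(all(sels$perEpoch == sels$perEpoch[1]))
})

test_that("stability check returns the companion spectral radius", {
    m <- makeGroundTruth(3, diagAR = 0.5)
    expect_equal(checkStability(m), 0.5, tolerance = 1e-12)
    expect_equal(checkStability(unidirNet()), 0.9, tolerance = 1e-12)
    expect_equal(checkStability(makeGroundTruth(2, diagAR = 0)), 0)
})

test_that("residuals are white when the model is correctly specified", {
    net <- order3Net()
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 8,
                         samplingRate = 500, seed = 41)
    X <- epochMatrix(es, 1)
    p <- 3
    m <- fitMVAR(X, p)
    # rebuild residuals from the fitted coefficients
    Tn <- ncol(X)
    pred <- matrix(0, nrow(X), Tn - p)
    for (l in 1:p)
        pred <- pred + coefArray(m)[, , l] %*% X[, (p + 1 - l):(Tn - l)]
    resid <- X[, (p + 1):Tn] - pred
    N <- ncol(resid)
    ok <- sapply(1:nrow(X), function(c) {
        ac <- acf(resid[c, ], lag.max = 5, plot = FALSE)$acf[-1]
        all(abs(ac) < 2 / sqrt(N))
    })
    expect_gte(mean(ok), 0.9)
})
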