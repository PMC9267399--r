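test_that("transfer function identities hold", {
    # zero dynamics: H is the identity at every frequency
    zero <- new("MVARModel", coef = array(0, c(3, 3, 1)),
                noiseCov = diag(3), nSamples = 0,
                channelNames = paste0("ch", 1:3))
    H <- transferFunction(zero, freqs = c(0, 5, 10, 40), fs = 500)
    for (f in 1:4)
        expect_equal(H[, , f], diag(3) + 0i, ignore_attr = TRUE)

    # triangular coefficients give a triangular transfer matrix
    net <- unidirNet()
    Ht <- transferFunction(net, freqs = seq(1, 50, 0.5), fs = 500)
    expect_true(all(Ht[1, 2, ] == 0))

    # hand-inverted spot value at f = 0: Abar = [[0.1, 0], [-0.5, 0.2]]
    H0 <- transferFunction(net, freqs = 0, fs = 500)[, , 1]
    expect_equal(H0, matrix(c(10, 25, 0, 5) + 0i, 2, 2),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("DTF spectra are normalized and match hand arithmetic", {
    net <- unidirNet()
    H <- transferFunction(net, freqs = 0, fs = 500)
    g <- dtfSpectrum(H, freqs = 0, fs = 500)
    expect_equal(dtfValues(g)[2, 1, 1], 625 / 650, tolerance = 1e-12)
    expect_identical(dtfValues(g)[1, 2, 1], 0)

    # identity H: self-flow 1, cross 0
    gI <- dtfSpectrum(array(diag(2) + 0i, c(2, 2, 3)), freqs = c(1, 2, 3))
    expect_equal(dtfValues(gI), array(diag(2), c(2, 2, 3)),
                 ignore_attr = TRUE)

    # row normalization for arbitrary stable models, both code paths equal
    for (s in 1:20) {
        m <- randomStableModel(k = sample(2:6, 1), p = sample(1:3, 1),
                               seed = 100 + s)
        fr <- seq(1, 50, 0.5)
        g1 <- dtfFromModel(m, fr, fs = 500)
        g2 <- dtfSpectrum(transferFunction(m, fr, fs = 500), fr, fs = 500)
        expect_lt(max(abs(dtfValues(g1) - dtfValues(g2))), 1e-12)
        rs <- apply(dtfValues(g1), c(1, 3), sum)
        expect_lt(max(abs(rs - 1)), 1e-9)
    }
})

test_that("band aggregation uses half-open bins on the analysis grid", {
    # oracle: enumerate the default grid points in [lo, hi)
    fr <- defaultFrequencyGrid()
    expect_identical(fr[fr >= 1 & fr < 4],
                     c(1, 1.5, 2, 2.5, 3, 3.5))   # delta: 6 bins

    m <- randomStableModel(3, 2, seed = 7)
    g <- dtfFromModel(m, fr, fs = 500)
    bm <- bandAggregate(g)
    expect_named(bm, c("delta", "theta", "alpha", "beta", "broadband"))
    v <- dtfValues(g)
    deltaRef <- apply(v[, , fr >= 1 & fr < 4], c(1, 2), mean)
    expect_equal(bm$delta, deltaRef, ignore_attr = TRUE)
    bbRef <- apply(v[, , fr >= 1 & fr < 30], c(1, 2), mean)
    expect_equal(bm$broadband, bbRef, ignore_attr = TRUE)

    # constant-over-frequency spectra aggregate to that constant
    zero <- new("MVARModel", coef = array(0, c(2, 2, 1)),
                noiseCov = diag(2), nSamples = 0,
                channelNames = c("a", "b"))
    gz <- dtfFromModel(zero, fr, fs = 500)
    bz <- bandAggregate(gz)
    for (b in names(bz))
        expect_equal(bz[[b]], diag(2), ignore_attr = TRUE)

    expect_error(bandAggregate(g, data.frame(name = "hi", lo = 55, hi = 60)),
                 "no grid points")
})

test_that("the epoch median behaves element-wise", {
    mkband <- function(x) list(delta = matrix(x, 2, 2))
    eps <- list(mkband(0.1), mkband(0.2), mkband(0.9))
    expect_equal(epochMedian(eps)$delta[1, 1], 0.2)

    same <- list(mkband(0.3), mkband(0.3))
    expect_equal(epochMedian(same)$delta, matrix(0.3, 2, 2),
                 ignore_attr = TRUE)

    bad <- list(mkband(0.1), list(delta = matrix(0.1, 3, 3)))
    expect_error(epochMedian(bad), "shape")
})

test_that("estimated DTF recovers direction on the unidirectional model", {
    net <- unidirNet()
    es <- simulateEpochs(net, nEpochs = 20, epochLength = 2,
                         samplingRate = 500, seed = 71)
    arr <- epochBandMatrices(es, order = 1)
    med <- epochMedian(arr)
    # median over epochs sits near the analytic band DTF of the truth
    trueBand <- bandAggregate(dtfFromModel(net, fs = 500))
    expect_equal(med$broadband[2, 1], trueBand$broadband[2, 1],
                 tolerance = 0.15, ignore_attr = TRUE)
    expect_gt(med$broadband[2, 1], 0.3)
    # no spurious reverse flow
    for (b in names(med)) expect_lt(med[[b]][1, 2], 0.05)
})
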