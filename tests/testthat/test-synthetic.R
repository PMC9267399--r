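test_that("ground-truth construction verifies stability", {
    # no dynamics: pure white noise
    wn <- makeGroundTruth(2, diagAR = 0)
    expect_equal(checkStability(wn), 0)

    # triangular lag-1 system: companion eigenvalues are the diagonal
    net <- unidirNet()
    expect_equal(checkStability(net), 0.9, tolerance = 1e-12)

    # unit-root violation is an error, not a silent rescale
    expect_error(makeGroundTruth(2, diagAR = 1.1), "unstable")

    # ... unless auto-scaling is requested, which shrinks to radius <= 0.95
    sc <- makeGroundTruth(2, diagAR = 1.1, autoScale = TRUE)
    expect_lte(checkStability(sc), 0.95)

    expect_error(
        makeGroundTruth(2, rbind(couplingEdges(1, 2, 1, 0.2),
                                 couplingEdges(1, 2, 1, 0.3))),
        "duplicate")
    expect_error(makeGroundTruth(2, couplingEdges(1, 2, 3, 0.2), order = 2),
                 "lag exceeds")
    expect_error(makeGroundTruth(2, couplingEdges(1, 5, 1, 0.2)),
                 "out of range")
})

test_that("simulated epochs have the declared geometry and are reproducible", {
    wn <- makeGroundTruth(2, diagAR = 0)
    es <- simulateEpochs(wn, nEpochs = 20, epochLength = 2,
                         samplingRate = 500, seed = 42)
    expect_identical(dim(es@epochs), c(2L, 1000L, 20L))
    expect_equal(nEpochs(es), 20L)
    # per-channel per-epoch demeaning
    mns <- apply(es@epochs, c(1L, 3L), mean)
    expect_lt(max(abs(mns)), 1e-9 * stats::sd(es@epochs))

    es2 <- simulateEpochs(wn, nEpochs = 20, epochLength = 2,
                          samplingRate = 500, seed = 42)
    expect_identical(es@epochs, es2@epochs)

    expect_error(simulateEpochs(wn, burnIn = 10), "burnIn")
})

test_that("a lag-1 coupling shows up as lagged cross-correlation", {
    # oracle: sample cross-correlation on one long realization
    net <- unidirNet()
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 20,
                         samplingRate = 500, seed = 7)
    x <- epochMatrix(es, 1)
    n <- ncol(x)
    r <- cor(x[1, 1:(n - 1)], x[2, 2:n])
    expect_gt(r, 0.2)
})

test_that("accepted networks generate stationary output", {
    net <- controlTemplate()
    es <- simulateEpochs(net, nEpochs = 1, epochLength = 100,
                         samplingRate = 500, seed = 9)
    x <- epochMatrix(es, 1)
    half <- ncol(x) %/% 2
    v1 <- apply(x[, 1:half], 1, var)
    v2 <- apply(x[, (half + 1):ncol(x)], 1, var)
    expect_true(all(abs(v2 / v1 - 1) < 0.2))
})

test_that("cohorts carry correct sizes, labels and derived seeds", {
    spec <- cohortSpec(nPerGroup = c(control = 3, responder = 2,
                                     nonresponder = 2),
                       template = compactControlTemplate(),
                       effectEdges = compactEffectEdges(0.4),
                       nEpochs = 2, epochLength = 1, samplingRate = 100,
                       seed = 5)
    co <- simulateCohort(spec)
    expect_equal(nrow(co$subjects), 7L)
    expect_equal(table(co$subjects$group)[["control"]], 3L)
    expect_equal(table(co$subjects$group)[["nonresponder"]], 2L)
    expect_length(co$epochs, 7L)
    # deterministic derivation from the master seed
    co2 <- simulateCohort(spec)
    expect_identical(co$subjects$seed, co2$subjects$seed)
    expect_identical(co$epochs[[1]]@epochs, co2$epochs[[1]]@epochs)

    # responders and controls share one template; nonresponders differ only
    # by the prescribed effect edges
    expect_identical(co$networks$control, co$networks$responder)
    expect_gt(nrow(co$networks$nonresponder@edges),
              nrow(co$networks$control@edges))

    # effect size 0: all three groups share one topology
    null <- cohortSpec(nPerGroup = c(control = 2, responder = 2,
                                     nonresponder = 2),
                       template = compactControlTemplate(),
                       effectEdges = NULL, nEpochs = 2, epochLength = 1,
                       samplingRate = 100, seed = 5)
    conull <- simulateCohort(null)
    expect_identical(coefArray(conull$networks$nonresponder),
                     coefArray(conull$networks$control))
})
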