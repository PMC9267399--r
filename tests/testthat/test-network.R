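test_that("node grouping averages member channel pairs", {
    sch <- defaultNodeScheme()
    ch <- canonicalChannels()

    ones <- matrix(1, 19, 19, dimnames = list(ch, ch))
    g1 <- groupToNodes(ones, sch)
    off <- row(g1) != col(g1)
    expect_true(all(g1[off] == 1))

    # a single surviving channel edge T8 <- F7 spreads over the 3x3 pairs
    m <- matrix(0, 19, 19, dimnames = list(ch, ch))
    m["T8", "F7"] <- 0.9
    g2 <- groupToNodes(m, sch)
    expect_equal(g2["RT", "LT"], 0.1)
    expect_equal(sum(g2 != 0), 1L)

    # fully pruned input stays zero
    g0 <- groupToNodes(m * 0, sch)
    expect_true(all(g0 == 0))

    sub <- m[1:10, 1:10]
    expect_error(groupToNodes(sub, compactNodeScheme()), "missing")
})

test_that("flow summaries are consistent double-entry bookkeeping", {
    sch <- compactNodeScheme()
    nn <- nodeNames(sch)
    m <- matrix(0, 3, 3, dimnames = list(nn, nn))
    nc0 <- new("NodeConnectivity", matrices = list(theta = m),
               channelMedians = list(), pvals = list(), alpha = 0.05,
               scheme = sch)
    fl0 <- flowSummary(nc0)
    expect_true(all(fl0$inflow == 0 & fl0$outflow == 0 &
                    fl0$nodal_strength == 0))

    m["RT", "LT"] <- 0.3
    nc1 <- new("NodeConnectivity", matrices = list(theta = m),
               channelMedians = list(), pvals = list(), alpha = 0.05,
               scheme = sch)
    fl1 <- flowSummary(nc1)
    expect_equal(fl1$inflow[fl1$node == "RT"], 0.3)
    expect_equal(fl1$outflow[fl1$node == "LT"], 0.3)
    expect_equal(sum(fl1$inflow) + sum(fl1$outflow),
                 sum(fl1$nodal_strength))

    set.seed(3)
    r <- matrix(runif(9), 3, 3, dimnames = list(nn, nn))
    ncr <- new("NodeConnectivity", matrices = list(theta = r),
               channelMedians = list(), pvals = list(), alpha = 0.05,
               scheme = sch)
    flr <- flowSummary(ncr)
    expect_equal(sum(flr$inflow), sum(flr$outflow))
    expect_equal(flr$nodal_strength, flr$inflow + flr$outflow)
})

test_that("permutation pruning rejects unusable inputs", {
    net <- makeGroundTruth(3, diagAR = 0.3)
    es <- simulateEpochs(net, nEpochs = 4, epochLength = 1,
                         samplingRate = 200, seed = 1)
    expect_error(permutationPrune(es, 1, nPerm = 10), "at least 19")
    one <- new("EpochSet", epochs = es@epochs[, , 1, drop = FALSE],
               samplingRate = 200, channelNames = channelNames(es),
               epochLength = 1)
    expect_error(permutationPrune(one, 1, nPerm = 50), "at least 2 epochs")
})

test_that("a strong coupling survives pruning; pruned entries are zero", {
    net <- makeGroundTruth(3, couplingEdges(1, 2, 1, 0.5), diagAR = 0.5)
    es <- simulateEpochs(net, nEpochs = 20, epochLength = 2,
                         samplingRate = 500, seed = 5)
    pr <- permutationPrune(es, order = 1, nPerm = 100, seed = 6)
    expect_lte(pr$pvals$broadband[2, 1], 0.01)
    expect_gt(pr$pruned$broadband[2, 1], 0)
    # every suprathreshold p-value entry is exactly zero after pruning
    for (b in names(pr$pruned))
        expect_true(all(pr$pruned[[b]][pr$pvals[[b]] >= 0.05] == 0))
})

test_that("tightening alpha never increases a flow summary", {
    net <- compactControlTemplate()
    es <- simulateEpochs(net, nEpochs = 10, epochLength = 2,
                         samplingRate = 500, seed = 8)
    loose <- permutationPrune(es, 2, nPerm = 60, alpha = 0.2, seed = 9)
    tight <- permutationPrune(es, 2, nPerm = 60, alpha = 0.05, seed = 9)
    flLoose <- flowSummary(nodeConnectivity(loose, compactNodeScheme()))
    flTight <- flowSummary(nodeConnectivity(tight, compactNodeScheme()))
    expect_true(all(flTight$inflow <= flLoose$inflow + 1e-12))
    expect_true(all(flTight$outflow <= flLoose$outflow + 1e-12))
})

test_that("grouping is equivariant under consistent channel relabeling", {
    net <- compactControlTemplate()
    es <- simulateEpochs(net, nEpochs = 8, epochLength = 2,
                         samplingRate = 500, seed = 10)
    med <- epochMedian(epochBandMatrices(es, 2))
    base <- flowSummary(new("NodeConnectivity",
                            matrices = lapply(med, groupToNodes,
                                              scheme = compactNodeScheme()),
                            channelMedians = list(), pvals = list(),
                            alpha = 0.05, scheme = compactNodeScheme()))
    # permute channels in the data and the scheme consistently
    perm <- c(3, 1, 6, 2, 5, 4)
    es2 <- new("EpochSet", epochs = es@epochs[perm, , , drop = FALSE],
               samplingRate = 500,
               channelNames = channelNames(es)[perm], epochLength = 2)
    med2 <- epochMedian(epochBandMatrices(es2, 2))
    fl2 <- flowSummary(new("NodeConnectivity",
                           matrices = lapply(med2, groupToNodes,
                                             scheme = compactNodeScheme()),
                           channelMedians = list(), pvals = list(),
                           alpha = 0.05, scheme = compactNodeScheme()))
    expect_equal(base$inflow, fl2$inflow, tolerance = 1e-10)
    expect_equal(base$outflow, fl2$outflow, tolerance = 1e-10)
})
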