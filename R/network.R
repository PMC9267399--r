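# Node grouping, permutation pruning, and inflow/outflow summaries.

#' Construct a node scheme
#'
#' @param membership named list, node name -> character vector of member
#'   channels; the union must partition the montage in use
#' @return a [NodeScheme-class]
#' @export
nodeScheme <- function(membership) {
    new("NodeScheme", nodeNames = names(membership),
        membership = membership)
}

#' The default seven-node anatomical grouping of the 19-channel montage
#'
#' Left/right frontal, left/right temporal, left/right parieto-occipital
#' and midline, partitioning the 19 canonical 10-20 channels.
#'
#' @return a [NodeScheme-class]
#' @export
#' @examples
#' defaultNodeScheme()
defaultNodeScheme <- function() {
    nodeScheme(list(
        LF  = c("Fp1", "F3", "C3"),
        LT  = c("F7", "T7", "P7"),
        LPO = c("P3", "O1"),
        RF  = c("Fp2", "F4", "C4"),
        RT  = c("F8", "T8", "P8"),
        RPO = c("P4", "O2"),
        ML  = c("Fz", "Cz", "Pz")))
}

#' A compact three-node scheme on six channels
#'
#' A scaled-down montage (left temporal, right temporal, midline; two
#' channels each) used for fast end-to-end validation runs; the analysis
#' path is identical to the full seven-node scheme.
#'
#' @return a [NodeScheme-class]
#' @export
compactNodeScheme <- function() {
    nodeScheme(list(LT = c("F7", "T7"), RT = c("F8", "T8"),
                    ML = c("Fz", "Cz")))
}

#' Control template on the compact six-channel montage
#'
#' @param coupling weight of the weak background coupling (Fz -> Cz)
#' @return a [GroundTruthNetwork-class]
#' @export
compactControlTemplate <- function(coupling = 0.1) {
    ch <- c("F7", "T7", "F8", "T8", "Fz", "Cz")
    net <- makeGroundTruth(6, couplingEdges("Fz", "Cz", 1L, coupling),
                           diagAR = 0.55, order = 2, channelNames = ch)
    A <- coefArray(net)
    A2 <- A[, , 2L]; diag(A2) <- 0.25; A[, , 2L] <- A2
    model <- new("MVARModel", coef = A, noiseCov = net@model@noiseCov,
                 nSamples = 0, channelNames = ch)
    new("GroundTruthNetwork", model = model, edges = net@edges,
        innovationsSD = net@innovationsSD,
        spectralRadius = companionRadius(A), seed = NA_real_)
}

#' Effect edges into the right temporal node of the compact montage
#'
#' @param weight coupling weight for each left-to-right temporal edge
#' @return data.frame of coupling edges
#' @export
compactEffectEdges <- function(weight = 0.4) {
    g <- expand.grid(from = c("F7", "T7"), to = c("F8", "T8"),
                     stringsAsFactors = FALSE)
    couplingEdges(from = g$from, to = g$to, lag = 1L, weight = weight)
}

#' Permutation-surrogate significance pruning of DTF values
#'
#' Builds `nPerm` surrogate epoch sets by independently permuting the epoch
#' order of each channel — destroying cross-channel temporal alignment
#' while preserving every per-channel spectrum — and refits the full
#' model-to-band pipeline on each. For every ordered channel pair and band,
#' the one-sided p-value is
#' `(1 + #\{surrogate median >= observed median\}) / (1 + nPerm)`
#' (the add-one estimator, so p is never zero). Observed entries with
#' p >= alpha are set to exactly zero before node grouping.
#'
#' @param epochSet an [EpochSet-class] with at least 2 epochs
#' @param order MVAR model order for all fits
#' @param freqs analysis grid
#' @param bands band definition
#' @param nPerm number of surrogates (>= 19, so that p below 0.05 is
#'   reachable; default 500)
#' @param alpha pruning threshold
#' @param seed optional RNG seed for the surrogate permutations
#' @return list with `pvals` (band -> channel p-value matrix), `observed`
#'   and `pruned` (band -> median matrices, unpruned/pruned),
#'   `prunedEpochs` (the per-epoch array with pruned entries zeroed),
#'   `survival` (fraction of off-diagonal entries surviving, per band),
#'   `alpha`, `order`
#' @export
permutationPrune <- function(epochSet, order,
                             freqs = defaultFrequencyGrid(),
                             bands = defaultBands(), nPerm = 500,
                             alpha = 0.05, seed = NULL) {
    stopifnot(is(epochSet, "EpochSet"))
    E <- nEpochs(epochSet)
    if (E < 2L) stop("permutation surrogates need at least 2 epochs")
    if (nPerm < 19L)
        stop("nPerm must be at least 19: with fewer surrogates the ",
             "smallest attainable p-value exceeds 0.05")
    k <- nChannels(epochSet)
    ch <- channelNames(epochSet)

    obs4 <- epochBandMatrices(epochSet, order, freqs = freqs, bands = bands)
    obsMed <- epochMedian(obs4)
    nb <- length(obsMed)

    if (!is.null(seed)) set.seed(seed)
    perms <- array(0L, dim = c(E, k, nPerm))
    for (r in seq_len(nPerm))
        for (c in seq_len(k))
            perms[, c, r] <- sample.int(E)

    g <- usedGrid(freqs, bands)
    surr <- cpp_surrogate_band_medians(epochSet@epochs, as.integer(order),
                                       g$freqs, samplingRate(epochSet),
                                       g$bins, perms)

    pvals <- vector("list", nb); names(pvals) <- names(obsMed)
    pruned <- obsMed
    pruned4 <- obs4
    survival <- numeric(nb); names(survival) <- names(obsMed)
    off <- row(obsMed[[1L]]) != col(obsMed[[1L]])
    for (b in seq_len(nb)) {
        sm <- matrix(surr[, , b, ], nrow = k * k)
        cnt <- rowSums(sm >= as.vector(obsMed[[b]]))
        p <- matrix((1 + cnt) / (1 + nPerm), k, k,
                    dimnames = list(target = ch, source = ch))
        pvals[[b]] <- p
        kill <- p >= alpha
        m <- obsMed[[b]]; m[kill] <- 0; pruned[[b]] <- m
        for (e in seq_len(E)) {
            me <- pruned4[, , b, e]; me[kill] <- 0; pruned4[, , b, e] <- me
        }
        survival[b] <- mean(!kill[off])
    }
    list(pvals = pvals, observed = obsMed, pruned = pruned,
         prunedEpochs = pruned4, survival = survival, alpha = alpha,
         order = order)
}

#' Group a channel-level connectivity matrix into nodes
#'
#' The node-level entry (target N, source M), N != M, is the mean of the
#' channel-level values over all member pairs (i in N, j in M); the mean
#' (rather than the sum) keeps nodes of different sizes comparable. The
#' diagonal (within-node) entries average the cross-channel pairs inside a
#' node and are flagged as excluded from flow summaries.
#'
#' @param channelMatrix target x source matrix with channel dimnames
#' @param scheme a [NodeScheme-class] covering exactly those channels
#' @return node x node matrix (target x source)
#' @export
groupToNodes <- function(channelMatrix, scheme = defaultNodeScheme()) {
    ch <- rownames(channelMatrix)
    if (is.null(ch)) stop("channelMatrix needs channel dimnames")
    memb <- membership(scheme)
    missing <- setdiff(ch, unlist(memb))
    if (length(missing))
        stop("channel(s) missing from node scheme: ",
             paste(missing, collapse = ", "))
    absent <- setdiff(unlist(memb), ch)
    if (length(absent))
        stop("scheme channel(s) absent from matrix: ",
             paste(absent, collapse = ", "))
    nn <- nodeNames(scheme)
    out <- matrix(0, length(nn), length(nn),
                  dimnames = list(target = nn, source = nn))
    for (a in nn) for (b in nn) {
        ia <- match(memb[[a]], ch); ib <- match(memb[[b]], ch)
        sub <- channelMatrix[ia, ib, drop = FALSE]
        if (a == b) {
            selfpair <- outer(ia, ib, "==")
            out[a, b] <- mean(sub[!selfpair])
        } else out[a, b] <- mean(sub)
    }
    out
}

#' Assemble pruned node connectivity from a pruning result
#'
#' @param prune result of [permutationPrune()]
#' @param scheme a [NodeScheme-class]
#' @return a [NodeConnectivity-class]
#' @export
nodeConnectivity <- function(prune, scheme = defaultNodeScheme()) {
    mats <- lapply(prune$pruned, groupToNodes, scheme = scheme)
    new("NodeConnectivity", matrices = mats,
        channelMedians = prune$pruned, pvals = prune$pvals,
        alpha = prune$alpha, scheme = scheme)
}

#' Per-node inflow, outflow and nodal strength
#'
#' inflow(N) is the sum of pruned connectivity directed toward N from every
#' other node, outflow(N) the sum directed away from N, and nodal strength
#' their sum. Within-node (diagonal) entries are excluded.
#'
#' @param nodeConn a [NodeConnectivity-class], or a single node matrix
#' @return data.frame with columns band, node, inflow, outflow,
#'   nodal_strength
#' @export
flowSummary <- function(nodeConn) {
    mats <- if (is(nodeConn, "NodeConnectivity")) nodeMatrices(nodeConn)
            else list(band = as.matrix(nodeConn))
    res <- lapply(names(mats), function(b) {
        m <- mats[[b]]
        d <- m; diag(d) <- 0
        data.frame(band = b, node = rownames(m),
                   inflow = rowSums(d), outflow = colSums(d),
                   nodal_strength = rowSums(d) + colSums(d),
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}
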