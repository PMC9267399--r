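# Ground-truth MVAR networks and synthetic EEG cohorts.
#
# The simulator exists so that every downstream stage (order selection, DTF,
# permutation pruning, node flows, group tests) can be validated against a
# known generating process: stable MVAR dynamics with prescribed directed
# couplings, white Gaussian innovations, and optional additive observation
# noise.

resolveChannelIndex <- function(x, channelNames) {
    if (is.character(x)) {
        idx <- match(x, channelNames)
        if (anyNA(idx))
            stop("unknown channel name(s): ",
                 paste(x[is.na(idx)], collapse = ", "))
        return(idx)
    }
    as.integer(x)
}

#' Specify directed coupling edges for a ground-truth network
#'
#' @param from,to source and target channels (indices or names), recycled
#' @param lag positive lag (in samples) of each coupling
#' @param weight coefficient weight of each coupling
#' @return data.frame with columns from, to, lag, weight
#' @export
#' @examples
#' couplingEdges(from = 1, to = 2, lag = 1, weight = 0.5)
couplingEdges <- function(from, to, lag = 1L, weight = 0.3) {
    data.frame(from = from, to = to, lag = as.integer(lag), weight = weight,
               stringsAsFactors = FALSE)
}

#' Construct a stability-verified ground-truth MVAR network
#'
#' Builds the coefficient stack A_1..A_p from per-channel self-regression
#' (`diagAR` at lag 1) plus sparse cross-channel couplings, verifies that the
#' companion matrix has spectral radius below one, and records the
#' innovations scale. An unstable specification is an error unless
#' `autoScale` is set, in which case all coefficients are shrunk uniformly
#' until the spectral radius is at most 0.95.
#'
#' @param nChannels number of channels (>= 2)
#' @param edges coupling edges as returned by [couplingEdges()] (may be NULL)
#' @param diagAR lag-1 self-regression weight, scalar or one per channel
#' @param innovationsSD innovations standard deviation, scalar or per channel
#' @param order model order p; defaults to the largest edge lag (at least 1)
#' @param channelNames channel labels; default "ch1".."chk"
#' @param seed integer seed recorded with the network (not used here)
#' @param autoScale shrink weights instead of failing when unstable
#' @return a [GroundTruthNetwork-class]
#' @export
#' @examples
#' net <- makeGroundTruth(2, couplingEdges(1, 2, 1, 0.5), diagAR = c(0.9, 0.8))
#' checkStability(net)   # 0.9
makeGroundTruth <- function(nChannels, edges = NULL, diagAR = 0,
                            innovationsSD = 1, order = NULL,
                            channelNames = NULL, seed = NA_real_,
                            autoScale = FALSE) {
    if (nChannels < 2) stop("nChannels must be at least 2")
    if (is.null(channelNames))
        channelNames <- paste0("ch", seq_len(nChannels))
    if (is.null(edges))
        edges <- couplingEdges(integer(0), integer(0), integer(0), numeric(0))
    if (!all(is.finite(edges$weight))) stop("edge weights must be finite")
    if (nrow(edges)) {
        edges$from <- resolveChannelIndex(edges$from, channelNames)
        edges$to <- resolveChannelIndex(edges$to, channelNames)
        if (any(edges$lag < 1)) stop("edge lags must be positive")
        if (any(edges$from < 1 | edges$from > nChannels |
                edges$to < 1 | edges$to > nChannels))
            stop("edge channel index out of range")
        if (anyDuplicated(edges[c("from", "to", "lag")]))
            stop("duplicate (source, target, lag) coupling edges")
    }
    diagAR <- rep_len(diagAR, nChannels)
    innovationsSD <- rep_len(innovationsSD, nChannels)
    p <- if (is.null(order)) max(1L, edges$lag) else as.integer(order)
    if (nrow(edges) && max(edges$lag) > p)
        stop("edge lag exceeds declared model order")

    A <- array(0, dim = c(nChannels, nChannels, p))
    A1 <- A[, , 1L]; diag(A1) <- diagAR; A[, , 1L] <- A1
    for (r in seq_len(nrow(edges)))
        A[edges$to[r], edges$from[r], edges$lag[r]] <-
            A[edges$to[r], edges$from[r], edges$lag[r]] + edges$weight[r]

    rad <- companionRadius(A)
    if (rad >= 1) {
        if (!autoScale)
            stop(sprintf("unstable network: spectral radius %.3f >= 1 %s",
                         rad, "(set autoScale = TRUE to shrink weights)"))
        while (rad > 0.95) {
            A <- A * (0.95 / rad)
            rad <- companionRadius(A)
        }
    }

    model <- new("MVARModel", coef = A,
                 noiseCov = diag(innovationsSD^2, nChannels),
                 nSamples = 0, channelNames = channelNames)
    new("GroundTruthNetwork", model = model, edges = edges,
        innovationsSD = innovationsSD, spectralRadius = rad,
        seed = as.numeric(seed))
}

#' Simulate an epoch set from a ground-truth network
#'
#' Each epoch is drawn independently: fresh innovations and a fresh burn-in,
#' so epochs are exchangeable (as the permutation scheme downstream
#' assumes). Samples are demeaned per channel per epoch.
#'
#' @param network a [GroundTruthNetwork-class]
#' @param nEpochs number of epochs
#' @param epochLength epoch length in seconds
#' @param samplingRate sampling rate in Hz
#' @param burnIn burn-in samples discarded before each epoch (>= 100)
#' @param observationNoiseSD additive white observation noise (default 0,
#'   the noise-free regime DTF theory assumes)
#' @param seed optional RNG seed for reproducibility
#' @return an [EpochSet-class]
#' @export
#' @examples
#' net <- makeGroundTruth(2, diagAR = 0.5)
#' es <- simulateEpochs(net, nEpochs = 3, epochLength = 1, samplingRate = 100,
#'                      seed = 1)
#' nEpochs(es)
simulateEpochs <- function(network, nEpochs = 20, epochLength = 2,
                           samplingRate = 500, burnIn = 500,
                           observationNoiseSD = 0, seed = NULL) {
    stopifnot(is(network, "GroundTruthNetwork"))
    if (burnIn < 100) stop("burnIn must be at least 100 samples")
    if (samplingRate <= 0) stop("samplingRate must be positive")
    if (!is.null(seed)) set.seed(seed)
    A <- coefArray(network)
    k <- dim(A)[1L]
    n <- round(epochLength * samplingRate)
    out <- array(0, dim = c(k, n, nEpochs))
    for (e in seq_len(nEpochs)) {
        innov <- matrix(rnorm((burnIn + n) * k, sd = network@innovationsSD),
                        nrow = k)   # sd recycled per channel down columns
        x <- cpp_simulate_var(A, innov, n)
        if (observationNoiseSD > 0)
            x <- x + matrix(rnorm(k * n, sd = observationNoiseSD), nrow = k)
        out[, , e] <- x - rowMeans(x)
    }
    if (!all(is.finite(out)))
        stop("simulation produced non-finite samples (unstable network?)")
    new("EpochSet", epochs = out, samplingRate = samplingRate,
        channelNames = channelNames(network@model), epochLength = epochLength)
}

#' Default control-like 19-channel ground-truth template
#'
#' A stable order-2 network on the canonical 10-20 montage: moderate
#' per-channel self-regression (lag-1 weight 0.55, lag-2 weight 0.25, giving
#' a slowly decaying, low-frequency-weighted spectrum) and a fixed set of
#' weak intra-hemispheric couplings so that some genuine information flow
#' exists even in controls.
#'
#' @param nChannels 19 (default montage) or any k >= 2 (generic labels)
#' @param coupling weight of the weak background couplings
#' @return a [GroundTruthNetwork-class]
#' @export
controlTemplate <- function(nChannels = 19, coupling = 0.1) {
    if (nChannels == 19) {
        ch <- canonicalChannels()
        edges <- couplingEdges(
            from = c("O1", "O2", "P3", "P4", "Fz"),
            to   = c("P3", "P4", "C3", "C4", "Cz"),
            lag = 1L, weight = coupling)
    } else {
        ch <- paste0("ch", seq_len(nChannels))
        edges <- couplingEdges(from = 1, to = 2, lag = 1L, weight = coupling)
    }
    net <- makeGroundTruth(nChannels, edges = edges, diagAR = 0.55, order = 2,
                           channelNames = ch)
    A <- coefArray(net)
    A2 <- A[, , 2L]; diag(A2) <- 0.25
    A[, , 2L] <- A2
    rad <- companionRadius(A)
    model <- new("MVARModel", coef = A, noiseCov = net@model@noiseCov,
                 nSamples = 0, channelNames = ch)
    new("GroundTruthNetwork", model = model, edges = net@edges,
        innovationsSD = net@innovationsSD, spectralRadius = rad,
        seed = NA_real_)
}

#' Default effect edges: elevated flow into the right temporal region
#'
#' Extra lag-1 couplings from the left temporal channels (F7, T7, P7) into
#' the right temporal channels (F8, T8, P8), emulating a nonresponder-like
#' profile with increased right-temporal inflow and increased left-temporal
#' outflow. The default weight is chosen for detectability in small
#' validation cohorts, not for clinical realism.
#'
#' @param weight coupling weight applied to each of the nine edges
#' @return data.frame of coupling edges
#' @export
rightTemporalEffectEdges <- function(weight = 0.35) {
    src <- c("F7", "T7", "P7")
    dst <- c("F8", "T8", "P8")
    g <- expand.grid(from = src, to = dst, stringsAsFactors = FALSE)
    couplingEdges(from = g$from, to = g$to, lag = 1L, weight = weight)
}

applyEffectEdges <- function(template, effectEdges) {
    if (is.null(effectEdges) || nrow(effectEdges) == 0L) return(template)
    ch <- channelNames(template@model)
    edges <- template@edges
    eff <- effectEdges
    eff$from <- resolveChannelIndex(eff$from, ch)
    eff$to <- resolveChannelIndex(eff$to, ch)
    all_edges <- rbind(edges, eff)
    makeGroundTruth(length(ch), edges = all_edges,
                    diagAR = diag(coefArray(template)[, , 1L]),
                    innovationsSD = template@innovationsSD,
                    order = modelOrder(template), channelNames = ch,
                    autoScale = TRUE)
}

#' Specify a synthetic cohort
#'
#' Controls and responders are drawn from the same template network
#' (independent seeds, identical topology); nonresponders additionally carry
#' `effectEdges` — extra directed couplings emulating the pathological
#' connectivity profile. An effect size of zero (empty `effectEdges`) yields
#' a null cohort in which all three groups share one topology.
#'
#' @param nPerGroup named counts for control, responder, nonresponder
#' @param template control/responder [GroundTruthNetwork-class]
#' @param effectEdges extra couplings for the nonresponder template (a
#'   data.frame from [couplingEdges()], or NULL for a null cohort)
#' @param nEpochs,epochLength,samplingRate,burnIn epoch-set parameters
#' @param observationNoiseSD additive observation noise
#' @param seed master seed; per-subject seeds are derived deterministically
#' @return a list of class "CohortSpec"
#' @export
cohortSpec <- function(nPerGroup = c(control = 10, responder = 6,
                                     nonresponder = 6),
                       template = controlTemplate(),
                       effectEdges = rightTemporalEffectEdges(),
                       nEpochs = 20, epochLength = 2, samplingRate = 500,
                       burnIn = 500, observationNoiseSD = 0, seed = 1) {
    stopifnot(all(c("control", "responder", "nonresponder") %in%
                  names(nPerGroup)))
    nonresponderTemplate <- applyEffectEdges(template, effectEdges)
    structure(list(nPerGroup = nPerGroup, template = template,
                   nonresponderTemplate = nonresponderTemplate,
                   effectEdges = effectEdges, nEpochs = nEpochs,
                   epochLength = epochLength, samplingRate = samplingRate,
                   burnIn = burnIn, observationNoiseSD = observationNoiseSD,
                   seed = seed),
              class = "CohortSpec")
}

#' Simulate a full synthetic cohort
#'
#' Draws one epoch set per subject, with per-subject seeds derived
#' deterministically from the master seed, and returns subject metadata
#' alongside the epoch sets and the generating networks.
#'
#' @param spec a [cohortSpec()]
#' @return list with elements `subjects` (data.frame: id, group, seed),
#'   `epochs` (named list of [EpochSet-class]) and `networks`
#' @export
simulateCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    n <- spec$nPerGroup
    groups <- rep(c("control", "responder", "nonresponder"),
                  times = c(n[["control"]], n[["responder"]],
                            n[["nonresponder"]]))
    if (!length(groups)) stop("cohort has no subjects")
    set.seed(spec$seed)
    seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
    ids <- sprintf("%s%02d", substr(groups, 1, 1),
                   unlist(lapply(n[c("control", "responder", "nonresponder")],
                                 seq_len)))
    subjects <- data.frame(id = ids, group = groups, seed = seeds,
                           stringsAsFactors = FALSE)
    nets <- list(control = spec$template, responder = spec$template,
                 nonresponder = spec$nonresponderTemplate)
    epochs <- vector("list", nrow(subjects))
    names(epochs) <- subjects$id
    for (s in seq_len(nrow(subjects))) {
        epochs[[s]] <- simulateEpochs(
            nets[[subjects$group[s]]], nEpochs = spec$nEpochs,
            epochLength = spec$epochLength,
            samplingRate = spec$samplingRate, burnIn = spec$burnIn,
            observationNoiseSD = spec$observationNoiseSD,
            seed = subjects$seed[s])
    }
    list(subjects = subjects, epochs = epochs, networks = nets)
}
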