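#' The 19 canonical 10-20 scalp electrode labels
#'
#' Channel labels of the standard 19-electrode international 10-20 montage,
#' in the package's canonical order. Modern nomenclature is used for the
#' temporal chain (T7/T8/P7/P8); the legacy synonyms T3/T4/T5/T6 are mapped
#' onto these by [validateMontage()].
#'
#' @return Character vector of length 19.
#' @export
#' @examples
#' canonicalChannels()
canonicalChannels <- function() {
    c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
      "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz")
}

#' EpochSet: a stack of fixed-length multichannel EEG epochs
#'
#' The unit all estimation consumes: \code{n_epochs} artifact-free segments
#' of identical length, each a channels x time matrix in microvolts, with a
#' shared sampling rate and channel labels. Epochs are demeaned per channel.
#' Internally stored as a 3-d array with dimensions
#' (channel, time, epoch).
#'
#' @slot epochs numeric array, dim (n_channels, n_samples, n_epochs)
#' @slot samplingRate sampling rate in Hz
#' @slot channelNames channel labels, unique, length n_channels
#' @slot epochLength epoch length in seconds
#' @export
setClass("EpochSet",
    representation(epochs = "array", samplingRate = "numeric",
                   channelNames = "character", epochLength = "numeric"))

setValidity("EpochSet", function(object) {
    d <- dim(object@epochs)
    if (length(d) != 3L)
        return("epochs must be a 3-d (channel, time, epoch) array")
    if (d[1L] != length(object@channelNames))
        return("channel count does not match channelNames")
    if (anyDuplicated(object@channelNames))
        return("channel names must be unique")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        return("samplingRate must be a single positive number")
    if (d[2L] != round(object@epochLength * object@samplingRate))
        return("epoch sample count must equal round(epochLength * samplingRate)")
    if (!all(is.finite(object@epochs)))
        return("epochs contain non-finite samples")
    TRUE
})

#' EEGRecording: a continuous multichannel EEG recording
#'
#' A channels x time matrix of samples in microvolts with a common sampling
#' rate, unique channel labels, and free-form provenance metadata. Produced
#' by [readEDF()]; consumed by [bandpassFilter()] and [extractEpochs()].
#'
#' @slot samples numeric matrix, channels x time (microvolts)
#' @slot samplingRate sampling rate in Hz
#' @slot channelNames unique channel labels
#' @slot meta provenance list (file path, header fields, filter history)
#' @export
setClass("EEGRecording",
    representation(samples = "matrix", samplingRate = "numeric",
                   channelNames = "character", meta = "list"))

setValidity("EEGRecording", function(object) {
    if (nrow(object@samples) != length(object@channelNames))
        return("row count must match channelNames")
    if (anyDuplicated(object@channelNames))
        return("channel names must be unique")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        return("samplingRate must be a single positive number")
    if (!all(is.finite(object@samples)))
        return("samples must be finite")
    TRUE
})

#' MVARModel: a fitted or ground-truth multivariate autoregressive model
#'
#' Coefficient matrices A_1..A_p for the convention
#' x(t) = sum_l A_l x(t - l) + e(t), with innovations covariance Sigma_e.
#'
#' @slot coef numeric array, dim (k, k, p): A_l = coef[, , l], entry (i, j)
#'   is the influence of channel j at lag l on channel i
#' @slot noiseCov k x k innovations covariance (symmetric PSD)
#' @slot nSamples effective sample count used in estimation
#' @slot channelNames channel labels
#' @export
setClass("MVARModel",
    representation(coef = "array", noiseCov = "matrix",
                   nSamples = "numeric", channelNames = "character"))

setValidity("MVARModel", function(object) {
    d <- dim(object@coef)
    if (length(d) != 3L || d[1L] != d[2L])
        return("coef must be a (k, k, p) array")
    if (!all(is.finite(object@coef)))
        return("coefficients must be finite")
    if (!isTRUE(all.equal(dim(object@noiseCov), d[1:2], check.attributes = FALSE)))
        return("noiseCov dimension does not match coefficient matrices")
    if (max(abs(object@noiseCov - t(object@noiseCov))) > 1e-8 * (1 + max(abs(object@noiseCov))))
        return("noiseCov must be symmetric")
    ev <- eigen(0.5 * (object@noiseCov + t(object@noiseCov)),
                symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
        return("noiseCov must be positive semi-definite")
    if (length(object@channelNames) && length(object@channelNames) != d[1L])
        return("channelNames length does not match k")
    TRUE
})

#' GroundTruthNetwork: a prescribed MVAR generating process
#'
#' A stability-verified MVAR network used to simulate EEG-like epoch sets
#' with known directed couplings: sparse cross-channel edges
#' (source, target, lag, weight) on top of per-channel self-regression, with
#' white Gaussian innovations.
#'
#' @slot model the [MVARModel-class] holding the full coefficient stack
#' @slot edges data.frame with columns from, to, lag, weight (the prescribed
#'   cross-channel couplings; from/to are channel indices)
#' @slot innovationsSD per-channel innovations standard deviation
#' @slot spectralRadius spectral radius of the companion matrix (< 1)
#' @slot seed integer seed recorded at construction (NA if unset)
#' @export
setClass("GroundTruthNetwork",
    representation(model = "MVARModel", edges = "data.frame",
                   innovationsSD = "numeric", spectralRadius = "numeric",
                   seed = "numeric"))

setValidity("GroundTruthNetwork", function(object) {
    k <- dim(object@model@coef)[1L]
    if (length(object@innovationsSD) != k)
        return("innovationsSD must have one value per channel")
    if (any(object@innovationsSD <= 0))
        return("innovationsSD must be positive")
    if (object@spectralRadius >= 1)
        return("network is unstable (spectral radius >= 1)")
    TRUE
})

#' DTFResult: normalized squared DTF spectra
#'
#' gamma^2_{i<-j}(f) on a frequency grid: the share of channel i's inflow at
#' frequency f attributable to channel j. For every target i and frequency,
#' the source row sums to one.
#'
#' @slot values numeric array, dim (target, source, frequency), in [0, 1]
#' @slot frequencies grid frequencies in Hz, strictly increasing
#' @slot samplingRate sampling rate in Hz (grid must stay below Nyquist)
#' @slot channelNames channel labels
#' @export
setClass("DTFResult",
    representation(values = "array", frequencies = "numeric",
                   samplingRate = "numeric", channelNames = "character"))

setValidity("DTFResult", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || d[1L] != d[2L])
        return("values must be a (target, source, frequency) array")
    if (d[3L] != length(object@frequencies))
        return("frequency dimension does not match grid")
    if (is.unsorted(object@frequencies, strictly = TRUE))
        return("frequencies must be strictly increasing")
    if (max(object@frequencies) >= object@samplingRate / 2)
        return("grid frequencies must stay below Nyquist")
    if (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12)
        return("DTF values must lie in [0, 1]")
    rs <- apply(object@values, c(1L, 3L), sum)
    if (max(abs(rs - 1)) > 1e-9)
        return("DTF source rows must sum to 1 per target and frequency")
    TRUE
})

#' NodeScheme: grouping of channels into anatomical nodes
#'
#' An ordered set of node names with a membership map assigning every
#' channel to exactly one node (a partition of the montage).
#'
#' @slot nodeNames ordered node labels
#' @slot membership named list, node -> character vector of member channels
#' @export
setClass("NodeScheme",
    representation(nodeNames = "character", membership = "list"))

setValidity("NodeScheme", function(object) {
    if (!identical(names(object@membership), object@nodeNames))
        return("membership must be named by nodeNames, in order")
    ch <- unlist(object@membership, use.names = FALSE)
    if (anyDuplicated(ch))
        return("membership must be disjoint (a channel appears twice)")
    if (any(lengths(object@membership) == 0L))
        return("every node needs at least one member channel")
    TRUE
})

#' NodeConnectivity: pruned node-level directed connectivity per band
#'
#' Node x node directed connectivity matrices per frequency band, obtained
#' by averaging permutation-pruned channel-level DTF over member-channel
#' pairs, together with the per-channel-pair permutation p-values and the
#' pruning threshold. Entries pruned at p >= alpha are exactly zero; the
#' diagonal (within-node) entries are stored but excluded from flow
#' summaries.
#'
#' @slot matrices named list, band -> node x node matrix (target x source)
#' @slot channelMedians named list, band -> pruned channel-level median
#'   matrices (target x source)
#' @slot pvals named list, band -> channel-level permutation p-value matrix
#' @slot alpha pruning significance threshold
#' @slot scheme the [NodeScheme-class] used for grouping
#' @export
setClass("NodeConnectivity",
    representation(matrices = "list", channelMedians = "list",
                   pvals = "list", alpha = "numeric", scheme = "NodeScheme"))

setValidity("NodeConnectivity", function(object) {
    if (!identical(names(object@matrices), names(object@pvals)) &&
        length(object@pvals))
        return("band names of matrices and pvals must agree")
    nn <- object@scheme@nodeNames
    for (b in names(object@matrices)) {
        m <- object@matrices[[b]]
        if (!identical(dim(m), c(length(nn), length(nn))))
            return("node matrix dimension does not match scheme")
        if (any(m < 0)) return("connectivity must be nonnegative")
    }
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
        return("alpha must be in (0, 1]")
    TRUE
})
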