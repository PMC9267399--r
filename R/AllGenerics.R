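# Accessor generics and show methods for the package's S4 containers.

#' @describeIn EpochSet-class channel labels
#' @param object,x an object of the documented class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @export
#' @describeIn EpochSet-class sampling rate in Hz
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @export
#' @describeIn EpochSet-class number of epochs
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @export
#' @describeIn EpochSet-class number of channels
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @export
#' @describeIn EpochSet-class one epoch as a channel x time matrix
#' @param i epoch index
setGeneric("epochMatrix", function(object, i) standardGeneric("epochMatrix"))

#' @export
#' @describeIn MVARModel-class model order p
setGeneric("modelOrder", function(object) standardGeneric("modelOrder"))

#' @export
#' @describeIn MVARModel-class coefficient array (k, k, p)
setGeneric("coefArray", function(object) standardGeneric("coefArray"))

#' @export
#' @describeIn MVARModel-class innovations covariance
setGeneric("noiseCov", function(object) standardGeneric("noiseCov"))

#' @export
#' @describeIn DTFResult-class DTF value array (target, source, frequency)
setGeneric("dtfValues", function(object) standardGeneric("dtfValues"))

#' @export
#' @describeIn DTFResult-class grid frequencies in Hz
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @export
#' @describeIn NodeScheme-class node labels
setGeneric("nodeNames", function(object) standardGeneric("nodeNames"))

#' @export
#' @describeIn NodeScheme-class node -> member-channel map
setGeneric("membership", function(object) standardGeneric("membership"))

#' @export
#' @describeIn NodeConnectivity-class band -> node matrix list
setGeneric("nodeMatrices", function(object) standardGeneric("nodeMatrices"))

#' @export
#' @describeIn NodeConnectivity-class band -> channel-pair p-value list
setGeneric("edgePValues", function(object) standardGeneric("edgePValues"))

#' @exportMethod channelNames
setMethod("channelNames", "EpochSet", function(object) object@channelNames)
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
setMethod("channelNames", "MVARModel", function(object) object@channelNames)
setMethod("channelNames", "DTFResult", function(object) object@channelNames)
setMethod("channelNames", "GroundTruthNetwork",
          function(object) object@model@channelNames)

#' @exportMethod samplingRate
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)
setMethod("samplingRate", "DTFResult", function(object) object@samplingRate)
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)

setMethod("nChannels", "EEGRecording", function(object) nrow(object@samples))

setMethod("show", "EEGRecording", function(object) {
    cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s @ %g Hz)\n",
                nrow(object@samples), ncol(object@samples),
                ncol(object@samples) / object@samplingRate,
                object@samplingRate))
})

#' @exportMethod nEpochs
setMethod("nEpochs", "EpochSet", function(object) dim(object@epochs)[3L])

#' @exportMethod nChannels
setMethod("nChannels", "EpochSet", function(object) dim(object@epochs)[1L])
setMethod("nChannels", "MVARModel", function(object) dim(object@coef)[1L])

#' @exportMethod epochMatrix
setMethod("epochMatrix", "EpochSet", function(object, i) {
    m <- object@epochs[, , i, drop = FALSE]
    dim(m) <- dim(object@epochs)[1:2]
    rownames(m) <- object@channelNames
    m
})

#' @exportMethod modelOrder
setMethod("modelOrder", "MVARModel", function(object) dim(object@coef)[3L])
setMethod("modelOrder", "GroundTruthNetwork",
          function(object) modelOrder(object@model))

#' @exportMethod coefArray
setMethod("coefArray", "MVARModel", function(object) object@coef)
setMethod("coefArray", "GroundTruthNetwork",
          function(object) object@model@coef)

#' @exportMethod noiseCov
setMethod("noiseCov", "MVARModel", function(object) object@noiseCov)

#' @exportMethod dtfValues
setMethod("dtfValues", "DTFResult", function(object) object@values)

#' @exportMethod frequencies
setMethod("frequencies", "DTFResult", function(object) object@frequencies)

#' @exportMethod nodeNames
setMethod("nodeNames", "NodeScheme", function(object) object@nodeNames)
setMethod("nodeNames", "NodeConnectivity",
          function(object) object@scheme@nodeNames)

#' @exportMethod membership
setMethod("membership", "NodeScheme", function(object) object@membership)

#' @exportMethod nodeMatrices
setMethod("nodeMatrices", "NodeConnectivity", function(object) object@matrices)

#' @exportMethod edgePValues
setMethod("edgePValues", "NodeConnectivity", function(object) object@pvals)

setMethod("show", "EpochSet", function(object) {
    d <- dim(object@epochs)
    cat(sprintf("EpochSet: %d epochs x %d channels x %d samples (%.3g s @ %g Hz)\n",
                d[3L], d[1L], d[2L], object@epochLength, object@samplingRate))
    cat("channels:", paste(head(object@channelNames, 8L), collapse = ", "),
        if (d[1L] > 8L) "..." else "", "\n")
})

setMethod("show", "MVARModel", function(object) {
    d <- dim(object@coef)
    cat(sprintf("MVARModel: k = %d channels, order p = %d, N = %g samples\n",
                d[1L], d[3L], object@nSamples))
})

setMethod("show", "GroundTruthNetwork", function(object) {
    k <- nChannels(object@model)
    cat(sprintf(
        "GroundTruthNetwork: %d channels, order %d, %d coupling edge(s), spectral radius %.3f\n",
        k, modelOrder(object@model), nrow(object@edges),
        object@spectralRadius))
})

setMethod("show", "DTFResult", function(object) {
    d <- dim(object@values)
    cat(sprintf("DTFResult: %d x %d channels over %d frequencies (%.1f-%.1f Hz)\n",
                d[1L], d[2L], d[3L], min(object@frequencies),
                max(object@frequencies)))
})

setMethod("show", "NodeScheme", function(object) {
    cat("NodeScheme:", length(object@nodeNames), "nodes\n")
    for (n in object@nodeNames)
        cat(sprintf("  %-4s: %s\n", n,
                    paste(object@membership[[n]], collapse = ", ")))
})

setMethod("show", "NodeConnectivity", function(object) {
    cat(sprintf("NodeConnectivity: %d nodes, bands: %s (pruned at alpha = %g)\n",
                length(object@scheme@nodeNames),
                paste(names(object@matrices), collapse = ", "),
                object@alpha))
})
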