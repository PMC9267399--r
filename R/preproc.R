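# Preprocessing: band-pass filtering, montage validation, epoch extraction.

#' Zero-phase band-pass filter a recording
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the effective magnitude response is eighth order
#' and the phase response is zero — phase distortion would bias directed
#' estimates. Defaults follow standard clinical practice for resting scalp
#' EEG: 0.5-70 Hz.
#'
#' @param recording an [EEGRecording-class]
#' @param low,high band edges in Hz; 0 < low < high < Nyquist
#' @param order Butterworth order per pass
#' @return the filtered [EEGRecording-class]
#' @export
bandpassFilter <- function(recording, low = 0.5, high = 70, order = 4) {
    fs <- samplingRate(recording)
    if (low <= 0 || low >= high) stop("need 0 < low < high")
    if (high >= fs / 2) stop("high cutoff must be below Nyquist (fs/2)")
    bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    filt <- t(apply(recording@samples, 1L, function(x)
        signal::filtfilt(bf, x)))
    meta <- recording@meta
    meta$bandpass <- c(low = low, high = high, order = order)
    new("EEGRecording", samples = filt, samplingRate = fs,
        channelNames = channelNames(recording), meta = meta)
}

#' Normalize channel labels against the 10-20 montage
#'
#' Case-insensitive matching to the 19 canonical 10-20 labels, with the
#' legacy temporal-chain synonyms T3/T4/T5/T6 mapped to T7/T8/P7/P8.
#' Returns the canonical labels in canonical order; unknown labels and
#' missing required channels are errors.
#'
#' @param labels channel labels as found in a recording
#' @param required labels that must all be present (default: the full
#'   19-channel montage needed by the default node scheme); NULL to skip
#' @return canonical labels in canonical order, with attribute `"index"`
#'   giving each returned channel's position in `labels`
#' @export
#' @examples
#' validateMontage(c("fp1", "T3", "FZ"), required = NULL)
validateMontage <- function(labels, required = canonicalChannels()) {
    canon <- canonicalChannels()
    synonyms <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")
    up <- toupper(trimws(labels))
    hit <- match(up, toupper(canon))
    syn <- match(up, names(synonyms))
    hit[!is.na(syn)] <- match(synonyms[syn[!is.na(syn)]], canon)
    if (anyNA(hit))
        stop("unknown channel label(s): ",
             paste(labels[is.na(hit)], collapse = ", "))
    if (anyDuplicated(hit))
        stop("duplicate channel(s) after normalization: ",
             paste(canon[hit[duplicated(hit)]], collapse = ", "))
    if (!is.null(required)) {
        miss <- setdiff(required, canon[hit])
        if (length(miss))
            stop("missing required channel(s): ",
                 paste(miss, collapse = ", "))
    }
    ord <- order(hit)
    structure(canon[hit[ord]], index = ord)
}

#' Extract fixed-length artifact-free epochs from a recording
#'
#' Deterministic earliest-clean placement: non-overlapping, chronologically
#' ordered segments are taken from the start of the recording, skipping any
#' segment that intersects an interval of the reject mask. Each epoch is
#' demeaned per channel.
#'
#' @param recording an [EEGRecording-class]
#' @param epochLength epoch length in seconds
#' @param nEpochs number of epochs to extract
#' @param rejectMask optional data.frame with columns start_s, end_s marking
#'   stretches to exclude (e.g. hand-marked artifacts)
#' @return an [EpochSet-class]
#' @export
extractEpochs <- function(recording, epochLength = 2, nEpochs = 20,
                          rejectMask = NULL) {
    fs <- samplingRate(recording)
    L <- as.integer(round(epochLength * fs))
    Tn <- ncol(recording@samples)
    k <- nChannels(recording)
    starts <- integer(nEpochs)
    pos <- 0L   # 0-based sample index of the candidate epoch start
    got <- 0L
    while (got < nEpochs && pos + L <= Tn) {
        t0 <- pos / fs
        t1 <- (pos + L) / fs
        if (!is.null(rejectMask) && nrow(rejectMask)) {
            bad <- rejectMask$start_s < t1 & rejectMask$end_s > t0
            if (any(bad)) {
                pos <- as.integer(ceiling(max(rejectMask$end_s[bad]) * fs))
                next
            }
        }
        got <- got + 1L
        starts[got] <- pos
        pos <- pos + L
    }
    if (got < nEpochs)
        stop(sprintf(
            "insufficient clean data: %d of %d epochs of %.3g s available",
            got, nEpochs, epochLength))
    out <- array(0, dim = c(k, L, nEpochs))
    for (e in seq_len(nEpochs)) {
        seg <- recording@samples[, (starts[e] + 1L):(starts[e] + L),
                                 drop = FALSE]
        out[, , e] <- seg - rowMeans(seg)
    }
    es <- new("EpochSet", epochs = out, samplingRate = fs,
              channelNames = channelNames(recording),
              epochLength = epochLength)
    attr(es@epochs, "start_sample") <- starts
    es
}

#' Assemble an EpochSet directly from a channels x time matrix
#'
#' Convenience constructor for tests and simulations: slices a matrix into
#' consecutive epochs and demeans each per channel.
#'
#' @param samples channels x time numeric matrix
#' @param samplingRate sampling rate in Hz
#' @param epochLength epoch length in seconds
#' @param channelNames optional labels
#' @return an [EpochSet-class]
#' @export
asEpochSet <- function(samples, samplingRate, epochLength,
                       channelNames = NULL) {
    if (is.null(channelNames))
        channelNames <- paste0("ch", seq_len(nrow(samples)))
    rec <- new("EEGRecording", samples = samples,
               samplingRate = samplingRate, channelNames = channelNames,
               meta = list())
    extractEpochs(rec, epochLength = epochLength,
                  nEpochs = floor(ncol(samples) /
                                  round(epochLength * samplingRate)))
}
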