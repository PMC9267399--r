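# Minimal European Data Format (EDF) reader and writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian 16-bit integers, one contiguous block per signal
# per record, linearly rescaled between the digital and physical ranges.
# Only the subset needed here is supported: equal sampling rate across
# signals, no annotations, no discontinuous recordings.

edfField <- function(x, width) {
    s <- formatC(as.character(x), width = -width)
    substr(s, 1L, width)
}

#' Write a recording or epoch set to an EDF file
#'
#' Epoch sets are written as one data record per epoch (records are
#' contiguous, so reading the file back and re-cutting epochs of the same
#' length recovers the original segmentation). Samples are rescaled to the
#' 16-bit digital range per channel, which bounds the round-trip error at
#' one digital quantum.
#'
#' @param x an [EpochSet-class] or [EEGRecording-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEDF <- function(x, path) {
    if (is(x, "EpochSet")) {
        k <- nChannels(x)
        nrec <- nEpochs(x)
        recDur <- x@epochLength
        nsPerRec <- dim(x@epochs)[2L]
        dat <- matrix(x@epochs, nrow = k)        # channels x (time*epochs)
        labels <- channelNames(x)
    } else if (is(x, "EEGRecording")) {
        k <- nChannels(x)
        nrec <- 1L
        nsPerRec <- ncol(x@samples)
        recDur <- nsPerRec / x@samplingRate
        dat <- x@samples
        labels <- channelNames(x)
    } else stop("x must be an EpochSet or EEGRecording")

    physMax <- apply(abs(dat), 1L, max)
    physMax[physMax == 0] <- 1
    physMax <- signif(physMax, 7)  # must survive the 8-char ASCII field
    digMax <- 32767L

    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(
        edfField("0", 8), edfField("synthetic", 80), edfField("dtfconn", 80),
        edfField("01.01.26", 8), edfField("00.00.00", 8),
        edfField(256L * (1L + k), 8), edfField("", 44),
        edfField(nrec, 8), edfField(format(recDur, digits = 7), 8),
        edfField(k, 4))
    sig <- paste0(
        paste(vapply(labels, edfField, "", width = 16), collapse = ""),
        strrep(edfField("", 80), k),                      # transducer
        strrep(edfField("uV", 8), k),                     # physical dim
        paste(vapply(-physMax, edfField, "", width = 8), collapse = ""),
        paste(vapply(physMax, edfField, "", width = 8), collapse = ""),
        strrep(edfField(-digMax, 8), k),
        strrep(edfField(digMax, 8), k),
        strrep(edfField("", 80), k),                      # prefiltering
        strrep(edfField(nsPerRec, 8), k),
        strrep(edfField("", 32), k))
    writeChar(paste0(hdr, sig), con, eos = NULL)

    scale <- digMax / physMax
    for (r in seq_len(nrec)) {
        cols <- ((r - 1L) * nsPerRec + 1L):(r * nsPerRec)
        for (c in seq_len(k)) {
            dig <- as.integer(round(dat[c, cols] * scale[c]))
            writeBin(dig, con, size = 2L, endian = "little")
        }
    }
    invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Channel order is preserved from the file and samples are rescaled to
#' physical units. Files with duplicate channel labels or with differing
#' per-channel sampling rates are rejected.
#'
#' @param path path to an EDF/EDF+ continuous file
#' @return an [EEGRecording-class]
#' @export
readEDF <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    rd <- function(w) {
        s <- readChar(con, w, useBytes = TRUE)
        if (length(s) != 1L || nchar(s, type = "bytes") < w)
            stop("corrupt EDF header in ", path)
        trimws(s)
    }
    version <- rd(8); rd(80); rd(80); rd(8); rd(8)
    headerBytes <- suppressWarnings(as.integer(rd(8)))
    rd(44)
    nrec <- suppressWarnings(as.integer(rd(8)))
    recDur <- suppressWarnings(as.numeric(rd(8)))
    k <- suppressWarnings(as.integer(rd(4)))
    if (is.na(k) || is.na(nrec) || is.na(recDur) || is.na(headerBytes) ||
        k < 1L || nrec < 1L || recDur <= 0)
        stop("corrupt EDF header in ", path)
    labels <- trimws(vapply(seq_len(k), function(i) rd(16), ""))
    if (anyDuplicated(labels))
        stop("duplicate channel label(s): ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "))
    rd(80 * k); rd(8 * k)
    physMin <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
    physMax <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
    digMin <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
    digMax <- as.numeric(vapply(seq_len(k), function(i) rd(8), ""))
    rd(80 * k)
    nsPerRec <- as.integer(vapply(seq_len(k), function(i) rd(8), ""))
    rd(32 * k)
    if (any(is.na(c(physMin, physMax, digMin, digMax, nsPerRec))))
        stop("corrupt EDF signal header in ", path)
    if (length(unique(nsPerRec)) != 1L)
        stop("heterogeneous per-channel sampling rates are not supported")
    ns <- nsPerRec[1L]
    fs <- ns / recDur

    out <- matrix(0, nrow = k, ncol = ns * nrec)
    for (r in seq_len(nrec)) {
        cols <- ((r - 1L) * ns + 1L):(r * ns)
        for (c in seq_len(k)) {
            dig <- readBin(con, "integer", n = ns, size = 2L, signed = TRUE,
                           endian = "little")
            if (length(dig) < ns) stop("truncated EDF data in ", path)
            out[c, cols] <- physMin[c] + (dig - digMin[c]) *
                (physMax[c] - physMin[c]) / (digMax[c] - digMin[c])
        }
    }
    new("EEGRecording", samples = out, samplingRate = fs,
        channelNames = labels,
        meta = list(path = path, edf_version = version, n_records = nrec,
                    record_duration_s = recDur))
}
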