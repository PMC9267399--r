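# Directed transfer function spectra, frequency grid and band aggregation.

#' Default analysis frequency grid
#'
#' Every 0.5 Hz from 1 to 50 Hz — the grid on which DTF is evaluated. The
#' gamma range (30-50 Hz) is present on the grid but excluded from the
#' default bands and all downstream statistics.
#'
#' @param from,to,by grid limits and step in Hz
#' @return numeric vector of frequencies
#' @export
defaultFrequencyGrid <- function(from = 1, to = 50, by = 0.5) {
    seq(from, to, by = by)
}

#' Default frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30 and broadband 0.5-30 Hz.
#' Bands are half-open intervals `[lo, hi)` so shared boundaries are never
#' double-counted, and each band is intersected with the analysis grid:
#' since the default grid starts at 1 Hz, delta and broadband effectively
#' begin at 1 Hz. The gamma range is deliberately absent.
#'
#' @return data.frame with columns name, lo, hi
#' @export
defaultBands <- function() {
    data.frame(name = c("delta", "theta", "alpha", "beta", "broadband"),
               lo = c(0.5, 4, 8, 12, 0.5),
               hi = c(4, 8, 12, 30, 30),
               stringsAsFactors = FALSE)
}

bandBins <- function(freqs, bands) {
    bins <- lapply(seq_len(nrow(bands)), function(b) {
        which(freqs >= bands$lo[b] & freqs < bands$hi[b])
    })
    names(bins) <- bands$name
    empty <- lengths(bins) == 0L
    if (any(empty))
        stop("band(s) with no grid points: ",
             paste(bands$name[empty], collapse = ", "))
    bins
}

# Restrict a grid to the frequencies any band actually uses (the gamma
# range sits on the default grid but no band covers it) and remap the band
# bins onto the reduced grid.
usedGrid <- function(freqs, bands) {
    bins <- bandBins(freqs, bands)
    used <- sort(unique(unlist(bins)))
    list(freqs = as.numeric(freqs[used]),
         bins = lapply(bins, function(ix) match(ix, used)))
}

modelCoef <- function(model) {
    if (is(model, "GroundTruthNetwork")) coefArray(model) else model@coef
}

#' Transfer matrix H(f) of an MVAR model on a frequency grid
#'
#' H(f) is the inverse of A_bar(f) = I - sum_l A_l exp(-i 2 pi f l / fs).
#' For triangular coefficient stacks the inverse is computed by
#' substitution, so structurally-absent couplings remain exactly zero. A
#' warning is issued for unstable models (spectral radius >= 1).
#'
#' @param model an [MVARModel-class] or [GroundTruthNetwork-class]
#' @param freqs evaluation frequencies in Hz
#' @param fs sampling rate in Hz
#' @return complex array, dim (target, source, frequency)
#' @export
transferFunction <- function(model, freqs = defaultFrequencyGrid(),
                             fs = 500) {
    A <- modelCoef(model)
    if (companionRadius(A) >= 1)
        warning("model is unstable (spectral radius >= 1); ",
                "DTF spectra are not interpretable")
    H <- cpp_transfer(A, as.numeric(freqs), fs)
    dimnames(H) <- list(channelNames(model), channelNames(model), NULL)
    H
}

#' Normalized squared DTF from a transfer matrix
#'
#' gamma^2_{i<-j}(f) = |H_ij(f)|^2 / sum_m |H_im(f)|^2: the fraction of the
#' total inflow to target i at frequency f that originates from source j.
#' Every target row therefore sums to one at every frequency.
#'
#' @param H complex (target, source, frequency) array from
#'   [transferFunction()]
#' @param freqs the grid frequencies of `H`
#' @param fs sampling rate in Hz
#' @return a [DTFResult-class]
#' @export
dtfSpectrum <- function(H, freqs, fs = 500) {
    if (!all(is.finite(Re(H)) & is.finite(Im(H))))
        stop("transfer matrix contains non-finite values")
    num <- Re(H)^2 + Im(H)^2
    den <- apply(num, c(1L, 3L), sum)
    if (any(den == 0)) {
        bad <- which(den == 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("all-zero transfer row for channel %d at f = %g",
                     bad[1L], freqs[bad[2L]]))
    }
    g <- num / aperm(array(den, dim = dim(num)[c(1L, 3L, 2L)]),
                     c(1L, 3L, 2L))
    ch <- dimnames(H)[[1L]]
    if (is.null(ch)) ch <- paste0("ch", seq_len(dim(H)[1L]))
    new("DTFResult", values = g, frequencies = as.numeric(freqs),
        samplingRate = fs, channelNames = ch)
}

#' Normalized squared DTF of a model in one step
#'
#' Convenience composition of [transferFunction()] and [dtfSpectrum()]
#' through the compiled path used by the pipeline.
#'
#' @inheritParams transferFunction
#' @return a [DTFResult-class]
#' @export
dtfFromModel <- function(model, freqs = defaultFrequencyGrid(), fs = 500) {
    A <- modelCoef(model)
    if (companionRadius(A) >= 1)
        warning("model is unstable (spectral radius >= 1); ",
                "DTF spectra are not interpretable")
    g <- cpp_dtf(A, as.numeric(freqs), fs)
    new("DTFResult", values = g, frequencies = as.numeric(freqs),
        samplingRate = fs, channelNames = channelNames(model))
}

#' Aggregate a DTF spectrum into frequency bands
#'
#' Mean (default) or median of gamma^2 over the grid frequencies falling in
#' each half-open band interval `[lo, hi)`.
#'
#' @param dtf a [DTFResult-class]
#' @param bands data.frame with columns name, lo, hi (default
#'   [defaultBands()])
#' @param statistic "mean" or "median" over the band's grid bins
#' @return named list, band -> target x source matrix
#' @export
bandAggregate <- function(dtf, bands = defaultBands(),
                          statistic = c("mean", "median")) {
    statistic <- match.arg(statistic)
    stopifnot(is(dtf, "DTFResult"))
    bins <- bandBins(frequencies(dtf), bands)
    v <- dtfValues(dtf)
    ch <- channelNames(dtf)
    lapply(bins, function(idx) {
        m <- apply(v[, , idx, drop = FALSE], c(1L, 2L),
                   if (statistic == "mean") mean else stats::median)
        dimnames(m) <- list(target = ch, source = ch)
        m
    })
}

#' Per-epoch band-aggregated DTF matrices for an epoch set
#'
#' Fits an MVAR model of the given order to every epoch and returns the
#' band-mean gamma^2 matrices, as a (channel, channel, band, epoch) array.
#'
#' @param epochSet an [EpochSet-class]
#' @param order MVAR model order used for every epoch
#' @param freqs analysis grid (default [defaultFrequencyGrid()])
#' @param bands band definition (default [defaultBands()])
#' @return numeric array, dim (k, k, n_bands, n_epochs), with dimnames
#' @export
epochBandMatrices <- function(epochSet, order,
                              freqs = defaultFrequencyGrid(),
                              bands = defaultBands()) {
    stopifnot(is(epochSet, "EpochSet"))
    g <- usedGrid(freqs, bands)
    out <- cpp_epoch_band(epochSet@epochs, as.integer(order),
                          g$freqs, samplingRate(epochSet), g$bins)
    dimnames(out) <- list(channelNames(epochSet), channelNames(epochSet),
                          names(g$bins), NULL)
    out
}

#' Element-wise median of band matrices across epochs
#'
#' The per-subject connectivity statistic: the median over epochs of the
#' band-aggregated DTF matrices. Accepts the 4-d array produced by
#' [epochBandMatrices()] (possibly already pruned, with pruned entries set
#' to zero) or a list of per-epoch band-matrix lists.
#'
#' @param x (k, k, band, epoch) array or list of band -> matrix lists
#' @return named list, band -> target x source median matrix
#' @export
epochMedian <- function(x) {
    if (is.list(x)) {
        bandsN <- names(x[[1L]])
        stopifnot(!is.null(bandsN))
        for (e in x)
            if (!identical(names(e), bandsN) ||
                !all(vapply(e, function(m)
                    identical(dim(m), dim(x[[1L]][[1L]])), TRUE)))
                stop("band matrices differ in shape across epochs")
        dn <- dimnames(x[[1L]][[1L]])
        if (is.null(dn)) dn <- list(NULL, NULL)
        x <- array(unlist(x),
                   dim = c(dim(x[[1L]][[1L]]), length(bandsN), length(x)),
                   dimnames = c(dn, list(bandsN, NULL)))
    }
    stopifnot(length(dim(x)) == 4L)
    bandsN <- dimnames(x)[[3L]]
    out <- lapply(seq_along(bandsN), function(b)
        apply(x[, , b, , drop = FALSE], c(1L, 2L), stats::median))
    names(out) <- bandsN
    out
}
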