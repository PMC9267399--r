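# MVAR estimation, Schwarz-Bayesian order selection, stability checks.

companionMatrix <- function(A) {
    k <- dim(A)[1L]; p <- dim(A)[3L]
    C <- matrix(0, k * p, k * p)
    for (l in seq_len(p))
        C[1:k, ((l - 1L) * k + 1L):(l * k)] <- A[, , l]
    if (p > 1L)
        C[(k + 1L):(k * p), 1:(k * (p - 1L))] <- diag(k * (p - 1L))
    C
}

companionRadius <- function(A) {
    if (all(A == 0)) return(0)
    max(Mod(eigen(companionMatrix(A), only.values = TRUE)$values))
}

epochAsMatrix <- function(epoch, i = NULL) {
    if (is(epoch, "EpochSet")) {
        if (is.null(i)) stop("epoch index required for an EpochSet")
        return(epochMatrix(epoch, i))
    }
    as.matrix(epoch)
}

#' Fit an MVAR model to one epoch by least squares
#'
#' Ordinary least squares on the stacked regression of x(t) on
#' x(t-1), ..., x(t-p) for t = p+1..T, solved through a QR decomposition
#' (no normal-equations inversion). The innovations covariance is the
#' residual cross-product divided by N - p*k, with N = T - p effective
#' samples.
#'
#' @param epoch a channels x time matrix (demeaned), or an
#'   [EpochSet-class] with `i` selecting the epoch
#' @param p model order
#' @param i epoch index when `epoch` is an EpochSet
#' @return an [MVARModel-class]
#' @export
#' @examples
#' net <- makeGroundTruth(2, couplingEdges(1, 2, 1, 0.5), diagAR = c(0.9, 0.8))
#' es <- simulateEpochs(net, nEpochs = 1, epochLength = 10, samplingRate = 500,
#'                      seed = 1)
#' fitMVAR(es, p = 1, i = 1)
fitMVAR <- function(epoch, p, i = NULL) {
    X <- epochAsMatrix(epoch, i)
    k <- nrow(X); Tn <- ncol(X)
    if (Tn <= p * k + k + p)
        stop(sprintf("epoch too short: T = %d cannot support k = %d, p = %d",
                     Tn, k, p))
    sds <- apply(X, 1L, stats::sd)
    if (any(sds == 0)) {
        nm <- rownames(X)
        if (is.null(nm)) nm <- paste0("ch", seq_len(k))
        stop("constant (zero-variance) channel(s): ",
             paste(nm[sds == 0], collapse = ", "))
    }
    fit <- cpp_fit_mvar(X, as.integer(p), as.integer(p) + 1L)
    nm <- rownames(X)
    if (is.null(nm)) nm <- paste0("ch", seq_len(k))
    new("MVARModel", coef = fit$coef,
        noiseCov = 0.5 * (fit$sigma_ls + t(fit$sigma_ls)),
        nSamples = fit$N, channelNames = nm)
}

#' Schwarz's Bayesian criterion for one candidate order
#'
#' SBC(p) = ln det(Sigma_hat(p)) + (ln N / N) * p * k^2, where Sigma_hat is
#' the maximum-likelihood residual covariance (divisor N) and N = T - pMax,
#' so that all candidate orders are scored on the same sample span. Lower
#' is better. A non-positive-definite residual covariance yields +Inf with
#' a warning.
#'
#' @param epoch channels x time matrix, or [EpochSet-class] with `i`
#' @param p candidate order
#' @param pMax largest order in the candidate set (fixes the common span;
#'   defaults to `p`)
#' @param i epoch index when `epoch` is an EpochSet
#' @return SBC score (dimensionless)
#' @export
sbcScore <- function(epoch, p, pMax = p, i = NULL) {
    X <- epochAsMatrix(epoch, i)
    k <- nrow(X)
    if (pMax < p) stop("pMax must be at least p")
    fit <- cpp_fit_mvar(X, as.integer(p), as.integer(pMax) + 1L)
    N <- fit$N
    ld <- determinant(fit$sigma_ml, logarithm = TRUE)
    if (ld$sign <= 0) {
        warning("non-positive-definite residual covariance at p = ", p)
        return(Inf)
    }
    as.numeric(ld$modulus) + (log(N) / N) * p * k^2
}

#' Select the MVAR order for an epoch set
#'
#' Computes the SBC-minimizing order for every epoch over a candidate
#' range, then takes the median across epochs (rounded to the nearest
#' integer, ties toward the smaller order), so one order serves all epochs
#' of a subject.
#'
#' @param epochSet an [EpochSet-class]
#' @param pMin,pMax candidate order range
#' @return list with `order` (the selected order), `perEpoch` (per-epoch
#'   argmin orders) and `sbc` (epochs x candidates score matrix)
#' @export
selectOrder <- function(epochSet, pMin = 2, pMax = 15) {
    stopifnot(is(epochSet, "EpochSet"))
    if (pMin > pMax) stop("pMin must not exceed pMax")
    cand <- seq.int(pMin, pMax)
    E <- nEpochs(epochSet)
    scores <- matrix(NA_real_, E, length(cand),
                     dimnames = list(NULL, paste0("p", cand)))
    for (e in seq_len(E)) {
        X <- epochMatrix(epochSet, e)
        scores[e, ] <- tryCatch(
            vapply(cand, function(p) sbcScore(X, p, pMax = pMax), 0),
            error = function(err)
                stop(sprintf("epoch %d: %s", e, conditionMessage(err))))
    }
    perEpoch <- cand[apply(scores, 1L, which.min)]  # first min = smaller p
    med <- stats::median(perEpoch)
    selected <- if (med %% 1 == 0.5) floor(med) else round(med)
    list(order = as.integer(selected), perEpoch = perEpoch, sbc = scores)
}

#' Spectral radius of the companion matrix of an MVAR model
#'
#' The model is stable (stationary) when the returned radius is below one;
#' DTF spectra from unstable models are not interpretable. The pipeline
#' warns when the radius reaches one but leaves the decision to the caller.
#'
#' @param model an [MVARModel-class] or [GroundTruthNetwork-class]
#' @return spectral radius (dimensionless)
#' @export
#' @examples
#' m <- makeGroundTruth(2, diagAR = 0.5)
#' checkStability(m)   # 0.5
checkStability <- function(model) {
    A <- if (is(model, "GroundTruthNetwork")) coefArray(model)
         else model@coef
    companionRadius(A)
}
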