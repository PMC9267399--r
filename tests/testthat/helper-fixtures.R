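# Shared fixtures, built in code.

# 2-channel unidirectional network: 1 drives 2 at lag 1.
unidirNet <- function(weight = 0.5) {
    makeGroundTruth(2, couplingEdges(1, 2, 1, weight), diagAR = c(0.9, 0.8))
}

# 3-channel true-order-3 network for order-selection checks.
order3Net <- function() {
    makeGroundTruth(3, couplingEdges(from = c(1, 2), to = c(2, 3),
                                     lag = 3, weight = 0.35),
                    diagAR = 0.5, order = 3)
}

# Random stable MVAR model: random coefficients shrunk to a target radius.
randomStableModel <- function(k, p, radius = 0.8, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    A <- array(rnorm(k * k * p, sd = 0.4 / sqrt(k * p)), dim = c(k, k, p))
    r <- dtfconn:::companionRadius(A)
    while (r > radius) {
        A <- A * (radius / r)
        r <- dtfconn:::companionRadius(A)
    }
    new("MVARModel", coef = A, noiseCov = diag(k), nSamples = 0,
        channelNames = paste0("ch", seq_len(k)))
}

compactChannels <- c("F7", "T7", "F8", "T8", "Fz", "Cz")
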