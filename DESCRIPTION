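Package: dtfconn
Title: Directed Transfer Function Connectivity Analysis of Multichannel EEG
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Effective-connectivity analysis of multichannel scalp EEG with
    the directed transfer function (DTF). Fits multivariate autoregressive
    (MVAR) models to short quasi-stationary epochs, selects the model order
    by Schwarz's Bayesian criterion, computes normalized squared DTF spectra
    on a 0.5-Hz grid, prunes non-significant channel pairs by permutation
    surrogates, aggregates channels into anatomical node groups, and
    summarizes directed information flow as per-node inflow, outflow and
    nodal strength. Includes exact Wilcoxon rank-sum group comparison with
    Bonferroni correction, a ground-truth MVAR cohort simulator for
    validation, and minimal European Data Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
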