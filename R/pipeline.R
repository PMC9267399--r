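# Pipeline orchestration: configuration, per-subject analysis, cohort
# simulation to EDF, group comparison and node-graph figures.

#' Default pipeline configuration
#'
#' A declarative description of a full run: paths, preprocessing, model
#' order search, frequency grid, permutation pruning, node scheme, cohort
#' simulation and comparison settings. Any subset can be overridden; the
#' resolved configuration is written next to the outputs of every run.
#'
#' @param ... named overrides, e.g. `permutation = list(nPerm = 200)`
#' @return nested list of class "PipelineConfig"
#' @export
pipelineConfig <- function(...) {
    cfg <- list(
        paths = list(outputDir = "dtfconn-out"),
        preprocessing = list(low = 0.5, high = 70, epochLength = 2,
                             nEpochs = 20, bandpass = TRUE),
        model = list(order = NA, pMin = 2, pMax = 15),
        grid = list(from = 1, to = 50, by = 0.5),
        permutation = list(nPerm = 500, alpha = 0.05),
        scheme = "default",
        cohort = list(control = 10, responder = 6, nonresponder = 6,
                      samplingRate = 500, effectWeight = 0.35, seed = 1),
        comparison = list(alpha = 0.05, m = NA,
                          directions = c("inflow", "outflow")),
        seed = 1)
    over <- list(...)
    for (nm in names(over)) {
        if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
            cfg[[nm]][names(over[[nm]])] <- over[[nm]]
        else cfg[[nm]] <- over[[nm]]
    }
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipelineConfig()] fields
#' @return a "PipelineConfig" list
#' @export
readConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

resolveScheme <- function(scheme) {
    if (is(scheme, "NodeScheme")) return(scheme)
    if (is.list(scheme)) return(nodeScheme(scheme))
    switch(scheme,
           default = defaultNodeScheme(),
           compact = compactNodeScheme(),
           stop("unknown node scheme: ", scheme))
}

writeResolvedConfig <- function(cfg, dir) {
    yaml::write_yaml(unclass(cfg), file.path(dir, "config-resolved.yaml"))
}

#' Analyze one epoch set into pruned node flows
#'
#' The per-subject core of the pipeline: order selection (unless a fixed
#' order is given), permutation pruning of the band-aggregated DTF medians,
#' node grouping and flow summarization.
#'
#' @param epochSet an [EpochSet-class]
#' @param scheme a [NodeScheme-class]
#' @param order fixed MVAR order, or NULL/NA to select by SBC
#' @param pMin,pMax SBC search range when selecting
#' @param freqs,bands analysis grid and bands
#' @param nPerm,alpha permutation pruning settings
#' @param seed RNG seed for the surrogates
#' @return list with `flow` (data.frame), `nodeConn`
#'   ([NodeConnectivity-class]), `prune`, `order`, `stability` (median
#'   per-epoch spectral radius)
#' @export
analyzeEpochSet <- function(epochSet, scheme = defaultNodeScheme(),
                            order = NULL, pMin = 2, pMax = 15,
                            freqs = defaultFrequencyGrid(),
                            bands = defaultBands(), nPerm = 500,
                            alpha = 0.05, seed = NULL) {
    if (is.null(order) || is.na(order))
        order <- selectOrder(epochSet, pMin = pMin, pMax = pMax)$order
    rad <- stats::median(vapply(seq_len(nEpochs(epochSet)), function(e)
        checkStability(fitMVAR(epochSet, order, i = e)), 0))
    if (rad >= 1)
        warning("median per-epoch spectral radius >= 1; estimates unstable")
    prune <- permutationPrune(epochSet, order, freqs = freqs, bands = bands,
                              nPerm = nPerm, alpha = alpha, seed = seed)
    nc <- nodeConnectivity(prune, scheme = scheme)
    list(flow = flowSummary(nc), nodeConn = nc, prune = prune,
         order = order, stability = rad)
}

#' Simulate a cohort and write it out as EDF files
#'
#' Writes one EDF per subject (channel labels from the template montage), a
#' subject table CSV, the ground-truth networks as JSON, and the resolved
#' configuration.
#'
#' @param config a [pipelineConfig()]
#' @return invisibly, the subject table with file paths
#' @export
runSimulate <- function(config = pipelineConfig()) {
    dir <- config$paths$outputDir
    if (is.null(dir)) stop("config$paths$outputDir is required")
    dir.create(file.path(dir, "edf"), recursive = TRUE, showWarnings = FALSE)
    scheme <- resolveScheme(config$scheme)
    compact <- identical(config$scheme, "compact")
    template <- if (compact) compactControlTemplate() else controlTemplate()
    eff <- if (config$cohort$effectWeight > 0) {
        if (compact) compactEffectEdges(config$cohort$effectWeight)
        else rightTemporalEffectEdges(config$cohort$effectWeight)
    } else NULL
    spec <- cohortSpec(
        nPerGroup = c(control = config$cohort$control,
                      responder = config$cohort$responder,
                      nonresponder = config$cohort$nonresponder),
        template = template, effectEdges = eff,
        nEpochs = config$preprocessing$nEpochs,
        epochLength = config$preprocessing$epochLength,
        samplingRate = config$cohort$samplingRate,
        seed = config$cohort$seed)
    cohort <- simulateCohort(spec)
    subj <- cohort$subjects
    subj$file <- file.path(dir, "edf", paste0(subj$id, ".edf"))
    for (s in seq_len(nrow(subj)))
        writeEDF(cohort$epochs[[subj$id[s]]], subj$file[s])
    write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
    gt <- lapply(cohort$networks, function(n) list(
        channels = channelNames(n@model), order = modelOrder(n),
        spectral_radius = n@spectralRadius,
        edges = n@edges, innovations_sd = n@innovationsSD))
    jsonlite::write_json(gt, file.path(dir, "ground-truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeResolvedConfig(config, dir)
    message(sprintf("simulated %d subjects into %s", nrow(subj), dir))
    invisible(subj)
}

#' Analyze every subject of a simulated or recorded cohort
#'
#' Reads each subject's EDF, optionally band-pass filters, extracts epochs,
#' runs the MVAR-DTF-pruning-grouping chain and writes one flow-summary CSV
#' per subject plus a combined long-format table.
#'
#' @param config a [pipelineConfig()]; `config$paths$outputDir` must contain
#'   `subjects.csv` and the EDF files from [runSimulate()] (or equivalents)
#' @return invisibly, the combined long flow data.frame
#' @export
runAnalyze <- function(config = pipelineConfig()) {
    dir <- config$paths$outputDir
    subj <- read.csv(file.path(dir, "subjects.csv"),
                     stringsAsFactors = FALSE)
    scheme <- resolveScheme(config$scheme)
    freqs <- defaultFrequencyGrid(config$grid$from, config$grid$to,
                                  config$grid$by)
    dir.create(file.path(dir, "flows"), showWarnings = FALSE)
    rows <- vector("list", nrow(subj))
    for (s in seq_len(nrow(subj))) {
        id <- subj$id[s]
        rec <- tryCatch(readEDF(subj$file[s]), error = function(e)
            stop(sprintf("subject %s: %s", id, conditionMessage(e))))
        if (isTRUE(config$preprocessing$bandpass))
            rec <- bandpassFilter(rec, config$preprocessing$low,
                                  config$preprocessing$high)
        validateMontage(channelNames(rec),
                        required = unlist(membership(scheme)))
        es <- extractEpochs(rec,
                            epochLength = config$preprocessing$epochLength,
                            nEpochs = config$preprocessing$nEpochs)
        res <- analyzeEpochSet(es, scheme = scheme,
                               order = config$model$order,
                               pMin = config$model$pMin,
                               pMax = config$model$pMax, freqs = freqs,
                               nPerm = config$permutation$nPerm,
                               alpha = config$permutation$alpha,
                               seed = config$permutation$seed + s)
        message(sprintf(
            "subject %s: order %d, stability %.3f, survival %s", id,
            res$order, res$stability,
            paste(sprintf("%s=%.2f", names(res$prune$survival),
                          res$prune$survival), collapse = " ")))
        fl <- res$flow
        fl$subject <- id
        fl$group <- subj$group[s]
        write.csv(fl, file.path(dir, "flows", paste0(id, ".csv")),
                  row.names = FALSE)
        rows[[s]] <- fl
    }
    flows <- do.call(rbind, rows)
    write.csv(flows, file.path(dir, "flows.csv"), row.names = FALSE)
    writeResolvedConfig(config, dir)
    invisible(flows)
}

#' Compare groups and render node-graph figures
#'
#' Runs the Bonferroni-corrected rank-sum comparison for every direction
#' and group pair, writes the result tables, and renders one node-graph
#' figure per (group pair, direction, band) showing nodal strength as
#' circle diameter and significance as a thickened circle.
#'
#' @param config a [pipelineConfig()]; expects `flows.csv` from
#'   [runAnalyze()] in the output directory
#' @param pairs list of 2-vectors of group labels to compare; default
#'   responder/nonresponder vs control and vs each other
#' @param figures render PNG figures (set FALSE for headless speed)
#' @return invisibly, the combined comparison table
#' @export
runCompare <- function(config = pipelineConfig(),
                       pairs = list(c("nonresponder", "control"),
                                    c("responder", "control"),
                                    c("nonresponder", "responder")),
                       figures = TRUE) {
    dir <- config$paths$outputDir
    flows <- read.csv(file.path(dir, "flows.csv"),
                      stringsAsFactors = FALSE)
    have <- unique(flows$group)
    m <- config$comparison$m
    if (is.null(m) || is.na(m)) m <- NULL
    out <- list()
    for (pr in pairs) {
        if (!all(pr %in% have))
            stop(sprintf("group(s) %s absent; available: %s",
                         paste(setdiff(pr, have), collapse = ", "),
                         paste(have, collapse = ", ")))
        for (dirn in config$comparison$directions) {
            cmp <- compareGroups(flows, pr[1], pr[2], direction = dirn,
                                 alpha = config$comparison$alpha, m = m)
            cmp$group_a <- pr[1]; cmp$group_b <- pr[2]
            out[[length(out) + 1L]] <- cmp
        }
    }
    res <- do.call(rbind, out)
    write.csv(res, file.path(dir, "comparisons.csv"), row.names = FALSE)
    if (figures) {
        dir.create(file.path(dir, "figures"), showWarnings = FALSE)
        for (pr in pairs) for (dirn in config$comparison$directions) {
            sel <- res$group_a == pr[1] & res$group_b == pr[2] &
                res$direction == dirn
            for (b in unique(res$band[sel])) {
                fsub <- flows[flows$group == pr[1] & flows$band == b, ]
                agg <- stats::aggregate(
                    fsub[c("inflow", "outflow", "nodal_strength")],
                    by = list(node = fsub$node), FUN = mean)
                sig <- res$node[sel & res$band == b & res$significant]
                fn <- file.path(dir, "figures",
                                sprintf("%s-vs-%s_%s_%s.png", pr[1], pr[2],
                                        dirn, b))
                png(fn, width = 600, height = 600)
                plotNodeGraph(agg, direction = dirn, significant = sig,
                              main = sprintf("%s vs %s: %s, %s band",
                                             pr[1], pr[2], dirn, b))
                dev.off()
            }
        }
    }
    writeResolvedConfig(config, dir)
    invisible(res)
}

nodePositions <- function(nodes) {
    fixed <- list(LF = c(-0.45, 0.55), RF = c(0.45, 0.55),
                  LT = c(-0.85, 0.05), RT = c(0.85, 0.05),
                  LPO = c(-0.45, -0.6), RPO = c(0.45, -0.6),
                  ML = c(0, 0))
    if (all(nodes %in% names(fixed)))
        return(do.call(rbind, fixed[nodes]))
    ang <- seq(0, 2 * pi, length.out = length(nodes) + 1L)[-1L]
    cbind(0.8 * sin(ang), 0.8 * cos(ang))
}

#' Draw a node-graph summary of directed flow
#'
#' Head-schematic layout: one circle per node with diameter proportional to
#' nodal strength, colored blue for inflow and red for outflow; nodes with
#' a significant group difference are drawn with a thickened outline.
#' Optionally overlays directed edges colored by flow strength.
#'
#' @param flow data.frame with columns node, inflow, outflow,
#'   nodal_strength (one band)
#' @param direction "inflow" or "outflow" (sets the fill color)
#' @param significant node labels to mark with a thick outline
#' @param edges optional node x node matrix of directed flow to draw
#' @param main plot title
#' @export
plotNodeGraph <- function(flow, direction = "inflow",
                          significant = character(0), edges = NULL,
                          main = "") {
    nodes <- flow$node
    xy <- nodePositions(nodes)
    op <- par(mar = c(1, 1, 3, 1)); on.exit(par(op))
    plot(NA, xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15), asp = 1,
         axes = FALSE, xlab = "", ylab = "")
    title(main)
    symbols(0, 0, circles = 1.08, inches = FALSE, add = TRUE, fg = "grey70")
    if (!is.null(edges)) {
        pal <- colorRampPalette(c("grey85", "darkorange", "firebrick"))(100)
        mx <- max(edges[row(edges) != col(edges)], 1e-12)
        for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
            if (a == b || edges[a, b] == 0) next
            w <- edges[a, b] / mx
            arrows(xy[b, 1], xy[b, 2], xy[a, 1], xy[a, 2], length = 0.08,
                   col = pal[pmax(1L, ceiling(w * 100))], lwd = 1 + 2 * w)
        }
    }
    strength <- flow$nodal_strength
    rad <- 0.06 + 0.14 * strength / max(strength, 1e-12)
    fill <- if (direction == "inflow") "#3b6fb6" else "#c23b3b"
    lwd <- ifelse(nodes %in% significant, 5, 1.5)
    symbols(xy[, 1], xy[, 2], circles = rad, inches = FALSE, add = TRUE,
            bg = grDevices::adjustcolor(fill, 0.6), fg = fill, lwd = lwd)
    text(xy[, 1], xy[, 2], nodes, cex = 0.9)
    invisible(xy)
}
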