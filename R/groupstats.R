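# Responder classification, cohort summaries, exact Wilcoxon rank-sum and
# Bonferroni-corrected group comparison of flow summaries.

#' Classify VNS responsiveness from the seizure-reduction rate
#'
#' A responder is a patient whose mean seizure frequency at the 5-year
#' follow-up fell by at least 50% from the presurgical baseline; the
#' boundary value 50 is a responder. Negative values (worsening) are
#' nonresponders; missing values are "unlabeled".
#'
#' @param reductionPct percent seizure reduction (<= 100; negative allowed)
#' @return character vector: "responder", "nonresponder" or "unlabeled"
#' @export
#' @examples
#' classifyResponder(c(61, 33, 50, -24, NA))
classifyResponder <- function(reductionPct) {
    if (any(reductionPct > 100, na.rm = TRUE))
        stop("seizure reduction cannot exceed 100%")
    ifelse(is.na(reductionPct), "unlabeled",
           ifelse(reductionPct >= 50, "responder", "nonresponder"))
}

#' Clinical table of the VNS patient cohort
#'
#' Per-patient clinical characteristics (age, sex, epilepsy duration,
#' diagnosis, baseline seizure frequency, 5-year mean seizure-reduction
#' rate, responsiveness label) of the twelve VNS-implanted patients,
#' shipped as a plain CSV under `extdata`.
#'
#' @return data.frame, one row per patient
#' @export
#' @examples
#' head(patientTable())
patientTable <- function() {
    path <- system.file("extdata", "vns_cohort.csv", package = "dtfconn",
                        mustWork = TRUE)
    read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize a patient group
#'
#' Mean and sample standard deviation (n - 1 divisor) of age and disease
#' duration, reported to two decimals. With a single subject the SD is
#' undefined and reported as NA.
#'
#' @param records data.frame with columns `group`, `age_years` and
#'   optionally `duration_years`
#' @param group the group label to summarize
#' @return list with n, mean_age, sd_age, mean_duration, sd_duration
#' @export
cohortSummary <- function(records, group) {
    sub <- records[records$group == group, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no subjects in group: ", group)
    r2 <- function(x) round(x, 2)
    sdOrNA <- function(x) if (length(x) < 2L) NA_real_ else r2(sd(x))
    dur <- if ("duration_years" %in% names(sub)) sub$duration_years
           else NA_real_
    list(n = nrow(sub),
         mean_age = r2(mean(sub$age_years)), sd_age = sdOrNA(sub$age_years),
         mean_duration = if (all(is.na(dur))) NA_real_ else r2(mean(dur)),
         sd_duration = if (all(is.na(dur))) NA_real_ else sdOrNA(dur))
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Mid-ranks are used for ties. When the combined sample size is at most
#' 20 the two-sided p-value is computed exactly by enumerating all
#' \eqn{\binom{n_x+n_y}{n_x}} assignments of the (mid-)ranks to the first
#' sample and counting those whose rank sum is at least as far from its
#' null expectation as the observed one; this is valid with and without
#' ties. Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y numeric samples (both nonempty)
#' @return list with `U` (Mann-Whitney statistic of `x`), `W` (rank sum of
#'   `x`), `p` (two-sided), and `exact` (whether enumeration was used)
#' @export
#' @examples
#' rankSumExact(c(1, 2, 3), c(4, 5, 6))$p   # 0.1
rankSumExact <- function(x, y) {
    if (!length(x) || !length(y)) stop("both samples must be nonempty")
    nx <- length(x); ny <- length(y); n <- nx + ny
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)])
    U <- W - nx * (nx + 1) / 2
    E <- nx * (n + 1) / 2
    if (n <= 20L) {
        sums <- colSums(matrix(r[combn(n, nx)], nrow = nx))
        p <- mean(abs(sums - E) >= abs(W - E) - 1e-9)
        return(list(U = U, W = W, p = p, exact = TRUE))
    }
    tie <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    z <- (abs(W - E) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    list(U = U, W = W, p = p, exact = FALSE)
}

#' Compare flow summaries between two groups
#'
#' One Wilcoxon rank-sum test per (band, node) cell on the subject-level
#' flow values of one direction (inflow or outflow), with Bonferroni
#' correction over the family of all cells in that direction
#' (m = bands x nodes by default).
#'
#' @param flows long data.frame with columns subject, group, band, node and
#'   the flow directions (as produced by the pipeline: one row per subject
#'   x band x node)
#' @param groupA,groupB group labels to compare
#' @param direction "inflow", "outflow" or "nodal_strength"
#' @param alpha family-wise significance level
#' @param m Bonferroni family size; defaults to the number of (band, node)
#'   cells tested
#' @return data.frame with one row per (band, node): U, raw p, adjusted p
#'   (`min(1, p * m)`) and the significance flag `p_adj < alpha`
#' @export
compareGroups <- function(flows, groupA, groupB, direction = "inflow",
                          alpha = 0.05, m = NULL) {
    stopifnot(direction %in% c("inflow", "outflow", "nodal_strength"))
    for (g in c(groupA, groupB)) {
        ns <- length(unique(flows$subject[flows$group == g]))
        if (ns < 2L)
            stop(sprintf("group '%s' has %d subject(s); need at least 2 %s",
                         g, ns, paste0("(available groups: ",
                              paste(unique(flows$group), collapse = ", "),
                              ")")))
    }
    cells <- unique(flows[c("band", "node")])
    if (is.null(m)) m <- nrow(cells)
    res <- lapply(seq_len(nrow(cells)), function(i) {
        b <- cells$band[i]; nd <- cells$node[i]
        sel <- flows$band == b & flows$node == nd
        xa <- flows[[direction]][sel & flows$group == groupA]
        xb <- flows[[direction]][sel & flows$group == groupB]
        t <- rankSumExact(xa, xb)
        data.frame(direction = direction, band = b, node = nd,
                   nA = length(xa), nB = length(xb), U = t$U, p = t$p,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- pmin(1, res$p * m)
    res$significant <- res$p_adj < alpha
    attr(res, "m") <- m
    res
}
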