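test_that("responder classification follows the >= 50% reduction rule", {
    expect_identical(classifyResponder(61), "responder")
    expect_identical(classifyResponder(33), "nonresponder")
    expect_identical(classifyResponder(50), "responder")      # boundary in
    expect_identical(classifyResponder(-24), "nonresponder")  # worsening
    expect_identical(classifyResponder(NA), "unlabeled")
    expect_error(classifyResponder(120), "cannot exceed")
})

test_that("the shipped clinical table is internally consistent", {
    tab <- patientTable()
    expect_identical(nrow(tab), 12L)
    relabeled <- classifyResponder(tab$reduction_pct)
    expect_identical(relabeled, tolower(tab$responsiveness))
    expect_identical(sum(relabeled == "responder"), 6L)
})

test_that("cohort summaries use the n-1 standard deviation", {
    rec <- data.frame(group = rep(c("a", "b", "c"), c(6, 1, 3)),
                      age_years = c(35, 38, 55, 21, 35, 41, 30,
                                    40, 40, 40),
                      duration_years = c(29, 20, 29, 12, 15, 28, 5,
                                         1, 2, 3))
    sa <- cohortSummary(rec, "a")
    expect_equal(sa$mean_age, 37.5)
    expect_equal(sa$sd_age, 10.99)
    expect_true(is.na(cohortSummary(rec, "b")$sd_age))   # n = 1
    expect_equal(cohortSummary(rec, "c")$sd_age, 0)      # all equal
    expect_error(cohortSummary(rec, "zz"), "no subjects")
})

test_that("exact rank-sum enumeration matches independent references", {
    # most extreme separation of 3 vs 3: 2 of the 20 rank splits
    r <- rankSumExact(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$p, 0.1)
    expect_equal(r$U, 0)
    expect_true(r$exact)

    # identical samples are exchangeable
    expect_equal(rankSumExact(c(1, 2), c(1, 2))$p, 1)

    # hand-enumerated tie case: x = (1,1), y = (1,2), every split is
    # equally extreme under mid-ranks
    expect_equal(rankSumExact(c(1, 1), c(1, 2))$p, 1)

    # no-tie cases agree with the exact Wilcoxon distribution
    set.seed(42)
    for (rep in 1:25) {
        nx <- sample(2:6, 1); ny <- sample(2:6, 1)
        x <- rnorm(nx); y <- rnorm(ny)
        ours <- rankSumExact(x, y)
        ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
        expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
        expect_equal(ours$U, unname(ref$statistic))
    }
})

test_that("group comparison applies Bonferroni over the cell family", {
    set.seed(9)
    grid <- expand.grid(band = c("delta", "theta"), node = c("LT", "RT"),
                        subject = paste0("s", 1:12),
                        stringsAsFactors = FALSE)
    grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= 6,
                         "a", "b")
    grid$inflow <- rnorm(nrow(grid))
    # plant a complete separation in one cell
    sel <- grid$band == "theta" & grid$node == "RT"
    grid$inflow[sel & grid$group == "b"] <-
        grid$inflow[sel & grid$group == "b"] + 100
    cmp <- compareGroups(grid, "a", "b", "inflow")
    expect_identical(attr(cmp, "m"), 4L)
    expect_true(all(cmp$p_adj >= cmp$p))
    expect_true(all(cmp$p_adj <= 1))
    hit <- cmp[cmp$band == "theta" & cmp$node == "RT", ]
    expect_equal(hit$p, 2 / choose(12, 6))
    expect_true(hit$significant)

    solo <- grid
    solo$group[solo$subject %in% paste0("s", 2:6)] <- "b"
    expect_error(compareGroups(solo, "a", "b", "inflow"), "at least 2")
})
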