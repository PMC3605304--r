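cat2 <- builtinCatalog()

test_that("activity scores are additive over catalog values", {
    expect_equal(activityScore(c("*2", "*27"), "CYP2C19", cat2), 0.5)
    expect_equal(activityScore(c("*2+*27", "*1"), "CYP2C19", cat2), 1.0)
    expect_equal(activityScore(c("*1", "*1"), "CYP2D6", cat2), 2.0)
    expect_equal(activityScore(c("*2xN", "*1"), "CYP2D6", cat2), 3.0)
    expect_equal(activityScore(c("*17", "*41"), "CYP2D6", cat2), 1.0)
    nv <- c("novel(*2+2575C>A)" = 1.0)
    expect_equal(activityScore(c("novel(*2+2575C>A)", "*4"), "CYP2D6",
                               cat2, novelActivities = nv), 1.0)
})

test_that("activity-score thresholds bin phenotypes correctly", {
    expect_identical(classifyActivityScore(0.0), "PM")
    expect_identical(classifyActivityScore(0.5), "IM")
    expect_identical(classifyActivityScore(1.0), "IM")
    expect_identical(classifyActivityScore(1.5), "EM")
    expect_identical(classifyActivityScore(2.0), "EM")
    expect_identical(classifyActivityScore(2.5), "UM")
    expect_identical(classifyActivityScore(4.0), "UM")
    expect_error(classifyActivityScore(0.25), "multiple of 0.5")
    expect_error(classifyActivityScore(-0.5), "non-negative")
})

test_that("categorical rules reproduce the documented rows", {
    expect_identical(
        classifyAmpliChipRules(c("*1xN", "*1"), "CYP2D6", cat2)$label, "UM")
    expect_identical(
        classifyAmpliChipRules(c("*4", "*5"), "CYP2D6", cat2)$label, "PM")
    r <- classifyAmpliChipRules(c("*17", "*41"), "CYP2D6", cat2)
    expect_identical(r$label, "IM")
    expect_match(r$rule, "reduced")
    ## mixed normal/reduced resolves by AS
    expect_identical(
        classifyAmpliChipRules(c("*1", "*41"), "CYP2D6", cat2)$label, "EM")
    expect_identical(
        classifyAmpliChipRules(c("*5", "*41"), "CYP2D6", cat2)$label, "IM")
    ## increased paired with absent
    expect_identical(
        classifyAmpliChipRules(c("*2xN", "*4"), "CYP2D6", cat2)$label, "EM")
})

test_that("the two schemes disagree measurably on unknown-class alleles", {
    ## (*25, *4): AS = 1.0 + 0.0 -> IM, but the categorical rules see one
    ## functional allele -> EM
    as_lab <- classifyActivityScore(activityScore(c("*25", "*4"), "CYP2D6",
                                                  cat2))
    rule_lab <- classifyAmpliChipRules(c("*25", "*4"), "CYP2D6", cat2)$label
    expect_identical(as_lab, "IM")
    expect_identical(rule_lab, "EM")
    ## build the scheme-disagreement matrix across a spread of diplotypes
    pairs <- list(c("*1", "*1"), c("*1", "*41"), c("*17", "*41"),
                  c("*4", "*5"), c("*25", "*4"), c("*1xN", "*1"),
                  c("*2xN", "*4"), c("*10", "*5"))
    mat <- table(
        AS = vapply(pairs, function(p)
            classifyActivityScore(activityScore(p, "CYP2D6", cat2)),
            character(1)),
        rules = vapply(pairs, function(p)
            classifyAmpliChipRules(p, "CYP2D6", cat2)$label, character(1)))
    expect_true(sum(mat) == length(pairs))
    expect_true(any(mat[row(mat) != col(mat)] > 0) ||
                    !identical(rownames(mat), colnames(mat)))
})

test_that("phenotype rank is monotone in allele activity", {
    rank <- c(PM = 1, IM = 2, EM = 3, UM = 4)
    acts <- c("*5" = 0, "*41" = 0.5, "*1" = 1, "*1xN" = 2)
    nms <- names(acts)
    for (partner in nms)
        for (i in seq_along(nms))
            for (j in seq_along(nms)) {
                if (acts[i] >= acts[j]) next
                lo <- classifyActivityScore(
                    activityScore(c(nms[i], partner), "CYP2D6", cat2))
                hi <- classifyActivityScore(
                    activityScore(c(nms[j], partner), "CYP2D6", cat2))
                expect_lte(rank[[lo]], rank[[hi]])
            }
})

test_that("cohort phenotype tables tally per-sample phenotypes", {
    mkcall <- function(id, pair, stratum) {
        callSample(make_obs("CYP2D6"), cat2)  # template, replaced below
    }
    ## all-reference cohort is 100% EM
    calls <- lapply(1:6, function(i) callSample(make_obs("CYP2D6"), cat2))
    pt <- cohortPhenotypeTable(calls, rep("A", 6))
    expect_equal(pt["EM", "A"], 100)
    expect_equal(sum(pt[, "A"]), 100)
    ## all-deletion cohort is 100% PM
    calls5 <- lapply(1:4, function(i)
        callSample(make_obs("CYP2D6", deletionCopies = 2L), cat2))
    pt5 <- cohortPhenotypeTable(calls5, rep("B", 4))
    expect_equal(pt5["PM", "B"], 100)
    ## mixed synthetic cohort matches the direct per-sample tally
    sim <- simulateTruth(defaultCohortConfig("CYP2D6"), seed = 3)
    calls <- lapply(sim$truth$sample, function(id)
        callSample(sim$observations[[id]], cat2))
    pt <- cohortPhenotypeTable(calls, sim$truth$stratum)
    for (s in colnames(pt))
        for (lab in c("PM", "IM", "EM", "UM"))
            expect_equal(pt[lab, s],
                         phenotype_tally_oracle(calls, sim$truth$stratum,
                                                s, lab))
    expect_equal(unname(colSums(pt)), rep(100, ncol(pt)))
})
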