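cat2 <- builtinCatalog()

test_that("allele frequency tables count primary diplotypes", {
    calls <- lapply(sprintf("s%02d", 1:70), function(id) {
        obs <- observedGenotype(id, "CYP2D6",
            data.frame(label = getAllele(cat2, "CYP2D6", "*17")$keyVariants,
                       zygosity = "het"))
        callSample(obs, cat2)
    })
    ct <- alleleFrequencyTable(calls, rep("A", 70))
    expect_equal(unname(ct@denominators["A"]), 140)
    expect_equal(ct@frequencies["*1", "A"], 50)
    expect_equal(ct@frequencies["*17", "A"], 50)
    one <- list(callSample(observedGenotype("x", "CYP2D6", NULL,
                                            deletionCopies = 2L), cat2))
    ct1 <- alleleFrequencyTable(one, "Z")
    expect_equal(ct1@frequencies["*5", "Z"], 100)
})

test_that("frequencies on synthetic cohorts equal a direct tally", {
    sim <- simulateTruth(defaultCohortConfig("CYP2C19"), seed = 5)
    calls <- lapply(sim$truth$sample, function(id)
        callSample(sim$observations[[id]], cat2))
    ## substitute truth pairs for the caller output so the oracle counts
    ## the same objects (ambiguity classes aside)
    ct <- alleleFrequencyTable(calls, sim$truth$stratum)
    for (s in colnames(ct@frequencies)) {
        idx <- sim$truth$stratum == s
        called <- unlist(lapply(calls[idx], function(x) x@primary))
        for (al in rownames(ct@frequencies))
            expect_equal(ct@frequencies[al, s],
                         sum(called == al) / length(called) * 100)
    }
})

test_that("count reconstruction uses half-up rounding", {
    fr <- matrix(c(10.7, 0.7), ncol = 1,
                 dimnames = list(c("*5", "*46"), "A"))
    ct <- suppressWarnings(
        cohortTable(rbind(fr, "*1" = 88.6), c(A = 140), "CYP2D6"))
    cnt <- reconstructCounts(ct)
    expect_identical(cnt["*5", "A"], 15L)
    expect_identical(cnt["*46", "A"], 1L)
})

test_that("frequency-table round trip recovers exact counts", {
    sim <- simulateTruth(defaultCohortConfig("CYP2D6"), seed = 9)
    calls <- lapply(sim$truth$sample, function(id)
        callSample(sim$observations[[id]], cat2))
    ct <- alleleFrequencyTable(calls, sim$truth$stratum)
    cnt <- reconstructCounts(ct)
    for (s in colnames(cnt)) {
        idx <- sim$truth$stratum == s
        called <- unlist(lapply(calls[idx], function(x) x@primary))
        for (al in rownames(cnt))
            expect_identical(cnt[al, s], length(which(called == al)))
    }
})

test_that("functional-class breakdown pools unknown with normal", {
    counts <- c("*1" = 50, "*17" = 30, "*5" = 10, "*25" = 6, "*2xN" = 4)
    bd <- functionalClassBreakdown(counts, cat2, "CYP2D6")
    expect_equal(bd$count[bd$class == "absent"], 10)
    expect_equal(bd$count[bd$class == "decreased"], 30)
    expect_equal(bd$count[bd$class == "normal"], 56)
    expect_equal(bd$count[bd$class == "increased"], 4)
    expect_equal(attr(bd, "unknown_pooled"), 6)
    expect_equal(sum(bd$percent), 100)
    expect_error(functionalClassBreakdown(c("*zzz" = 1), cat2, "CYP2D6"),
                 "absent from catalog")
})

test_that("Fisher's exact 2x2 matches worked values and the oracle", {
    expect_equal(fisherExact2x2(1, 1, 1, 1), 1.0)
    expect_equal(fisherExact2x2(5, 0, 0, 5), 2 / choose(10, 5))
    expect_equal(fisherExact2x2(2, 0, 0, 2), 1 / 3)
    expect_error(fisherExact2x2(0, 0, 0, 0), "all-zero")
    ## spot equality with the enumeration oracle and stats::fisher.test
    set.seed(1)
    for (i in 1:25) {
        cells <- as.integer(rmultinom(1, sample(4:20, 1), rep(1 / 4, 4)))
        if (sum(cells) == 0) next
        p <- fisherExact2x2(cells[1], cells[2], cells[3], cells[4])
        expect_equal(p, fisher_oracle(cells[1], cells[2], cells[3],
                                      cells[4]), tolerance = 1e-12)
        expect_equal(p, stats::fisher.test(matrix(cells, 2))$p.value,
                     tolerance = 1e-7)
    }
})

test_that("biallelic HWE test equals enumeration and slot-space oracles", {
    expect_equal(hweExactTest(c("A/A" = 3, "A/a" = 4, "a/a" = 3)),
                 hwe_biallelic_oracle(3, 4, 3))
    expect_equal(hweExactTest(c("*1/*1" = 10)), 1.0)
    expect_error(hweExactTest(c("A/A" = 0)), "zero samples")
    ## the conditional-probability formula agrees with brute-force
    ## enumeration of allele placements for tiny n
    for (cfg in list(c(2, 1, 1), c(1, 2, 2), c(0, 4, 1), c(3, 0, 2))) {
        expect_equal(hwe_biallelic_oracle(cfg[1], cfg[2], cfg[3]),
                     hwe_slot_oracle(cfg[1], cfg[2], cfg[3]),
                     tolerance = 1e-9,
                     info = paste(cfg, collapse = ","))
        expect_equal(
            hweExactTest(c("A/A" = cfg[1], "A/a" = cfg[2], "a/a" = cfg[3])),
            hwe_slot_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-9)
    }
})

test_that("multi-allelic Monte Carlo HWE approximates the exhaustive oracle", {
    gc <- c("a/a" = 1, "a/b" = 2, "b/c" = 2, "c/c" = 1)
    exact <- hwe_multi_oracle(gc)
    mc <- hweExactTest(gc, seed = 42, nPermutations = 20000)
    expect_lt(abs(mc - exact), 0.02)
})

test_that("platform concordance reports agreement, p-values and miscalls", {
    df <- data.frame(sample = sprintf("s%03d", 1:100),
                     allele1 = "*1", allele2 = "*17",
                     stringsAsFactors = FALSE)
    self <- platformConcordance(df, df)
    expect_equal(self$agreement, 1.0)
    expect_equal(self$perAllele$p, rep(1.0, nrow(self$perAllele)),
                 tolerance = 1e-12)
    expect_true(all(self$miscallMatrix == 0))
    ## one differing sample out of 100
    df2 <- df
    df2$allele2[1] <- "*41"
    one <- platformConcordance(df, df2)
    expect_equal(one$agreement, 0.99)
    expect_identical(unname(one$miscallMatrix["*17", "*41"]), 1L)
    ## disjoint sample sets are an error
    df3 <- df; df3$sample <- paste0("x", df3$sample)
    expect_error(platformConcordance(df, df3), "disjoint")
    ## failed samples excluded and tallied
    df4 <- df; df4$status <- c("failure", rep("ok", 99))
    out <- platformConcordance(df4, df)
    expect_equal(out$nCompared, 99)
    expect_equal(unname(out$excluded["failedA"]), 1)
})
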