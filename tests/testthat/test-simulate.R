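cat2 <- builtinCatalog()

test_that("degenerate and deterministic simulation contracts hold", {
    cfg <- simulationConfig("CYP2D6", c(A = 20), list(A = c("*1" = 1)))
    sim <- simulateTruth(cfg, seed = 1)
    expect_true(all(sim$truth$allele1 == "*1" & sim$truth$allele2 == "*1"))
    ## same seed, identical cohorts
    cfg2 <- defaultCohortConfig("CYP2D6")
    s1 <- simulateTruth(cfg2, seed = 99)
    s2 <- simulateTruth(cfg2, seed = 99)
    expect_identical(s1$truth, s2$truth)
    expect_identical(names(s1$observations), names(s2$observations))
    expect_identical(s1$observations[["S0001"]]@calls,
                     s2$observations[["S0001"]]@calls)
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig("CYP2D6", c(A = 10),
                                  list(A = c("*zz" = 1))),
                 "missing from the catalog")
    expect_error(new("SimulationConfig", gene = "CYP2D6",
                     strataSizes = c(A = 10L),
                     frequencies = list(A = c("*1" = 0.5))) |>
                     validObject(),
                 "sum to 1")
})

test_that("sampled allele frequencies sit inside their binomial CI", {
    ## large single-stratum draw: *17 frequency within the exact 99% CI
    ## of the configured parameter
    cfg <- defaultCohortConfig("CYP2D6",
                               strataSizes = c(BlackAfrican = 10000,
                                               Caucasian = 1, Coloured = 1,
                                               Indian = 1))
    sim <- simulateTruth(cfg, seed = 202, withObservations = FALSE)
    p17 <- cfg@frequencies$BlackAfrican[["*17"]]
    black <- sim$truth$stratum == "BlackAfrican"
    n17 <- sum(c(sim$truth$allele1[black], sim$truth$allele2[black]) ==
                   "*17")
    ci <- stats::binom.test(n17, 20000, conf.level = 0.99)$conf.int
    expect_gt(p17, ci[1]); expect_lt(p17, ci[2])
})

test_that("frequency recovery holds across many seeded runs", {
    cfg <- simulationConfig("CYP2C19", c(A = 500),
                            list(A = c("*1" = 0.6, "*2" = 0.25,
                                       "*27" = 0.15)))
    inside <- 0L
    for (s in 1:100) {
        sim <- simulateTruth(cfg, seed = 5000 + s, withObservations = FALSE)
        n2 <- sum(c(sim$truth$allele1, sim$truth$allele2) == "*2")
        ci <- stats::binom.test(n2, 1000, conf.level = 0.99)$conf.int
        if (ci[1] < 0.25 && 0.25 < ci[2]) inside <- inside + 1L
    }
    expect_gte(inside, 95L)
})

test_that("HWE test calibrates to its nominal size on simulated truth", {
    ## biallelic locus drawn under HWE in a large stratum; the exact test
    ## should reject at the 0.05 level in about 5% of replicates
    cfg <- simulationConfig("CYP2C19", c(A = 5000),
                            list(A = c("*1" = 0.7, "*2" = 0.3)))
    rejections <- 0L
    nrep <- 200L
    for (s in seq_len(nrep)) {
        sim <- simulateTruth(cfg, seed = 300 + s, withObservations = FALSE)
        gt <- paste(pmin(sim$truth$allele1, sim$truth$allele2),
                    pmax(sim$truth$allele1, sim$truth$allele2), sep = "/")
        counts <- table(gt)
        p <- hweExactTest(stats::setNames(as.numeric(counts),
                                          names(counts)))
        if (p < 0.05) rejections <- rejections + 1L
    }
    rate <- rejections / nrep
    expect_gte(rate, 0.025)
    expect_lte(rate, 0.075)
})

test_that("simulated observations encode CNV evidence faithfully", {
    cfg <- simulationConfig("CYP2D6", c(A = 400),
                            list(A = c("*1" = 0.5, "*5" = 0.3,
                                       "*2xN" = 0.2)))
    sim <- simulateTruth(cfg, seed = 17)
    for (i in seq_len(nrow(sim$truth))) {
        pair <- c(sim$truth$allele1[i], sim$truth$allele2[i])
        o <- sim$observations[[sim$truth$sample[i]]]
        expect_identical(o@deletionCopies, sum(pair == "*5"))
        expect_identical(o@duplicationPresent, any(pair == "*2xN"))
        if (o@duplicationPresent)
            expect_identical(o@duplicatedAlleleHint, "*2")
        if (o@deletionCopies == 2L) expect_identical(nrow(o@calls), 0L)
    }
})

test_that("the error-free profile is the identity on cohorts", {
    sim <- simulateTruth(defaultCohortConfig("CYP2D6"), seed = 8)
    obs <- applyPlatformModel(sim, errorFreeProfile(), seed = 9)
    expect_identical(obs$observed$allele1, sim$truth$allele1)
    expect_identical(obs$observed$allele2, sim$truth$allele2)
    expect_true(all(obs$observed$status == "ok"))
})

test_that("documented array error modes fire as configured", {
    prof <- amplichipProfile(failureProb = 0, noCallProb = 0)
    ## uncovered alleles miscalled deterministically: *45B -> *41
    cfg <- simulationConfig("CYP2D6", c(A = 50),
                            list(A = c("*45B" = 0.5, "*46" = 0.5)))
    sim <- simulateTruth(cfg, seed = 4)
    out <- applyPlatformModel(sim, prof, seed = 5)
    expect_true(all(out$observed$allele1 == "*41" &
                        out$observed$allele2 == "*41"))
    ## heterozygous deletion dropout: (*17, *5) reported (*17, *17)
    prof2 <- amplichipProfile(deletionDropoutProb = 1, failureProb = 0,
                              noCallProb = 0)
    cfg2 <- simulationConfig("CYP2D6", c(A = 30),
                             list(A = c("*17" = 0.5, "*5" = 0.5)))
    sim2 <- simulateTruth(cfg2, seed = 6)
    out2 <- applyPlatformModel(sim2, prof2, seed = 7)
    het5 <- sim2$truth$allele1 == "*17" & sim2$truth$allele2 == "*5" |
        sim2$truth$allele1 == "*5" & sim2$truth$allele2 == "*17"
    expect_true(all(out2$observed$allele1[het5] == "*17" &
                        out2$observed$allele2[het5] == "*17"))
    ## failures / no-calls are emitted as such
    prof3 <- amplichipProfile(failureProb = 1)
    out3 <- applyPlatformModel(sim2, prof3, seed = 8)
    expect_true(all(out3$observed$status == "failure"))
    expect_true(all(is.na(out3$observed$allele1)))
})
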