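cat2 <- builtinCatalog()
d6_2 <- getAllele(cat2, "CYP2D6", "*2")

test_that("haplotype matching follows defining-SNP precedence", {
    ## *4 core variants
    expect_identical(matchHaplotype(c("100C>T", "1846G>A"), "CYP2D6", cat2),
                     "*4")
    ## empty set is the reference haplotype
    expect_identical(matchHaplotype(character(), "CYP2D6", cat2), "*1")
    ## *2 core plus the *41 key SNP wins as *41; without it, *2
    core <- d6_2$keyVariants
    expect_identical(matchHaplotype(c(core, "2988G>A"), "CYP2D6", cat2),
                     "*41")
    expect_identical(matchHaplotype(c(core, "-1584C>G"), "CYP2D6", cat2),
                     "*2")
    ## *2 backbone plus 4157T>G is *85
    expect_identical(
        matchHaplotype(c(core, d6_2$backboneVariants, "4157T>G"),
                       "CYP2D6", cat2), "*85")
    ## two equally sized maximal matches -> ambiguity error listing both
    expect_error(
        matchHaplotype(c("2850C>T", "4180G>C", "2988G>A", "1716G>A"),
                       "CYP2D6", cat2),
        "\\*41.*\\*45B|\\*45B.*\\*41")
})

test_that("novel alleles get backbone, extras and null-aware activity", {
    core <- d6_2$keyVariants
    ## a *84-like situation with an uncatalogued extra SNP: default 1.0
    nc <- detectNovel(c(core, "2575C>A"), "CYP2D6", cat2)
    expect_s4_class(nc, "NovelAlleleCandidate")
    expect_identical(nc@backbone, "*2")
    expect_identical(nc@extraVariants, "2575C>A")
    expect_equal(nc@assignedActivity, 1.0)
    ## a *4P-like situation: the 1846G>A splice defect forces 0.0
    nc0 <- detectNovel(c("100C>T", "1846G>A", "4158T>G"), "CYP2D6", cat2)
    expect_equal(nc0@assignedActivity, 0.0)
    expect_match(nc0@rationale, "1846G>A")
    ## fully matched set -> no candidate
    expect_null(detectNovel(c(core, "2988G>A"), "CYP2D6", cat2))
})

test_that("diplotype enumeration reproduces the *2 / *2+*27 ambiguity", {
    obs <- make_obs("CYP2C19", het = c("19154G>A", "-1401G>A"))
    prs <- enumerateDiplotypes(obs, cat2)
    labs <- vapply(prs, function(p) paste(pair_names(p), collapse = "/"),
                   character(1))
    expect_identical(labs, c("*2/*27", "*1/*2+*27"))
    ## homozygous splice defect + het promoter SNP: unique explanation
    obs2 <- make_obs("CYP2C19", hom = "19154G>A", het = "-1401G>A")
    prs2 <- enumerateDiplotypes(obs2, cat2)
    expect_identical(paste(pair_names(prs2[[1]]), collapse = "/"),
                     "*2/*2+*27")
    ## no variants -> homozygous reference
    prs3 <- enumerateDiplotypes(make_obs("CYP2C19"), cat2)
    expect_identical(pair_names(prs3[[1]]), c("*1", "*1"))
})

test_that("every enumerated pair re-validates and the list is never empty", {
    cfg <- defaultCohortConfig("CYP2D6")
    sim <- simulateTruth(cfg, seed = 7)
    for (o in sim$observations[1:30]) {
        prs <- enumerateDiplotypes(o, cat2)
        expect_gt(length(prs), 0)
        for (p in prs) {
            for (r in p) {
                if (is.null(r$novel)) {
                    hap <- union(getAllele(cat2, "CYP2D6",
                                           r$name)$keyVariants,
                                 character())
                    rematch <- matchHaplotype(hap, "CYP2D6", cat2,
                                              onAmbiguity = "first")
                    expect_identical(rematch, r$name)
                }
            }
        }
    }
})

test_that("CNV evidence overrides hom calls and attaches duplications", {
    a17 <- getAllele(cat2, "CYP2D6", "*17")
    obs <- make_obs("CYP2D6", hom = a17$keyVariants, deletionCopies = 1L)
    pairs <- enumerateDiplotypes(obs, cat2)
    res <- integrateCnv(pairs, obs, cat2)
    expect_identical(pair_names(res$pairs[[1]]), c("*5", "*17"))
    ## duplication hint carries xN into the pair
    obs2 <- make_obs("CYP2D6", het = d6_2$keyVariants,
                     duplicationPresent = TRUE,
                     duplicatedAlleleHint = "*2")
    res2 <- integrateCnv(enumerateDiplotypes(obs2, cat2), obs2, cat2)
    expect_true("*2xN" %in% pair_names(res2$pairs[[1]]))
    ## no CNV evidence leaves the input unchanged
    obs3 <- make_obs("CYP2D6")
    prs3 <- enumerateDiplotypes(obs3, cat2)
    expect_identical(integrateCnv(prs3, obs3, cat2)$pairs, prs3)
    ## conflicting phase sets with a single remaining copy -> error
    calls <- data.frame(label = c("100C>T", "2850C>T"), zygosity = "het",
                        phaseSet = c("p1", "p2"))
    obs4 <- observedGenotype("t", "CYP2D6", calls, deletionCopies = 1L)
    expect_error(integrateCnv(list(), obs4, cat2), "phase sets")
})

test_that("exon-9 conversion relabels *4 and *10 haplotypes", {
    mk <- function(names) lapply(names, function(nm)
        list(name = nm, novel = NULL,
             activity = activityOf(cat2, "CYP2D6", nm)))
    obs <- make_obs("CYP2D6", exon9Conversion = TRUE)
    r1 <- applyExon9Conversion(list(mk(c("*1", "*4"))), obs, cat2)
    expect_identical(pair_names(r1$pairs[[1]]), c("*1", "*4N"))
    r2 <- applyExon9Conversion(list(mk(c("*2", "*10"))), obs, cat2)
    expect_identical(pair_names(r2$pairs[[1]]), c("*2", "*36"))
    ## the relabelled alleles take the catalog's activity classes
    expect_equal(r1$pairs[[1]][[2]]$activity, 0.0)
    expect_equal(r2$pairs[[1]][[2]]$activity, 0.5)
    r3 <- applyExon9Conversion(list(mk(c("*1", "*1"))), obs, cat2)
    expect_identical(pair_names(r3$pairs[[1]]), c("*1", "*1"))
    expect_match(r3$notes, "no \\*4 or \\*10")
})

test_that("callSample handles trivial and forced cases deterministically", {
    cc <- callSample(make_obs("CYP2D6"), cat2)
    expect_identical(cc@primary, c("*1", "*1"))
    expect_equal(cc@activityScore, 2.0)
    expect_identical(cc@phenotype, "EM")
    cc5 <- callSample(make_obs("CYP2D6", deletionCopies = 2L), cat2)
    expect_identical(cc5@primary, c("*5", "*5"))
    expect_equal(cc5@activityScore, 0.0)
    expect_identical(cc5@phenotype, "PM")
    ## determinism: identical observation, identical call
    obs <- make_obs("CYP2D6", het = c("2850C>T", "4180G>C", "2988G>A"))
    c1 <- callSample(obs, cat2); c2 <- callSample(obs, cat2)
    expect_identical(c1@primary, c2@primary)
    expect_identical(c1@alternatives, c2@alternatives)
    expect_identical(c1@activityScore, c2@activityScore)
})

test_that("inconsistent CNV evidence yields no_call, not an error", {
    calls <- data.frame(label = c("100C>T", "2850C>T"), zygosity = "het",
                        phaseSet = c("p1", "p2"))
    obs <- observedGenotype("t", "CYP2D6", calls, deletionCopies = 1L)
    cc <- callSample(obs, cat2)
    expect_identical(cc@phenotype, "no_call")
    expect_match(cc@notes, "no_call:")
})

test_that("error-free simulated cohorts are recovered exactly", {
    for (gene in c("CYP2D6", "CYP2C19")) {
        cfg <- defaultCohortConfig(gene)
        sim <- simulateTruth(cfg, seed = 11)
        for (i in seq_len(nrow(sim$truth))) {
            id <- sim$truth$sample[i]
            cc <- callSample(sim$observations[[id]], cat2)
            truthPair <- c(sim$truth$allele1[i], sim$truth$allele2[i])
            expect_true(primary_or_alt_matches(cc, truthPair),
                        info = paste(gene, id,
                                     paste(truthPair, collapse = "/"),
                                     "got",
                                     paste(cc@primary, collapse = "/")))
        }
    }
})
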