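## Independent brute-force oracles used to freeze expected values.

## Fisher 2x2 oracle: explicit hypergeometric enumeration with
## choose()-product probabilities (margins fixed).
fisher_oracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
    xs <- max(0, c1 - r2):min(r1, c1)
    probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
    obs <- probs[xs == a]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

## Biallelic HWE oracle: probability of each heterozygote configuration
## conditional on allele counts, from explicit factorial products.
hwe_biallelic_oracle <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    w <- vapply(hs, function(h) {
        aa <- (nA - h) / 2; bb <- n - aa - h
        exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
                lfactorial(bb) + h * log(2))
    }, numeric(1))
    p <- w / sum(w)
    obs <- p[hs == nAB]
    min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

## Sample-space HWE oracle for tiny n: enumerate every placement of the A
## alleles among the 2n ordered slots, pair consecutive slots into
## genotypes, and tally heterozygote-count probabilities directly.
hwe_slot_oracle <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    nA <- 2 * nAA + nAB
    slots <- 2 * n
    combos <- utils::combn(slots, nA)
    het_obs <- nAB
    het_counts <- apply(combos, 2, function(ix) {
        v <- integer(slots); v[ix] <- 1L
        g <- v[seq(1, slots, 2)] + v[seq(2, slots, 2)]
        sum(g == 1L)
    })
    tab <- table(het_counts) / ncol(combos)
    obs <- tab[[as.character(het_obs)]]
    min(1, sum(tab[tab <= obs * (1 + 1e-7)]))
}

## Exhaustive multi-allelic HWE oracle: enumerate all distinct orderings
## of the allele multiset (equally likely under permutation), pair
## consecutive slots, and accumulate the probability of configurations
## whose conditional probability is <= the observed one.
hwe_multi_oracle <- function(genotype_counts) {
    parts <- strsplit(names(genotype_counts), "/", fixed = TRUE)
    vec <- unlist(mapply(function(p, k) rep(p, k), parts, genotype_counts,
                         SIMPLIFY = FALSE))
    n <- length(vec) / 2
    log_prob <- function(counts) {
        het <- sum(counts[vapply(strsplit(names(counts), "/", fixed = TRUE),
                                 function(p) p[1] != p[2], logical(1))])
        lfactorial(n) - sum(lfactorial(counts)) + het * log(2)
    }
    t_obs <- log_prob(tapply(genotype_counts, names(genotype_counts), sum))
    ## recursive enumeration of distinct multiset permutations
    total <- 0; hit <- 0
    counts_env <- new.env()
    rec <- function(remaining, seq_so_far) {
        if (length(remaining) == 0) {
            g <- paste(pmin(seq_so_far[c(TRUE, FALSE)],
                            seq_so_far[c(FALSE, TRUE)]),
                       pmax(seq_so_far[c(TRUE, FALSE)],
                            seq_so_far[c(FALSE, TRUE)]), sep = "/")
            tg <- table(g)
            t_sim <- log_prob(stats::setNames(as.numeric(tg), names(tg)))
            total <<- total + 1
            if (t_sim <= t_obs + 1e-7) hit <<- hit + 1
            return()
        }
        for (a in unique(remaining)) {
            i <- match(a, remaining)
            rec(remaining[-i], c(seq_so_far, a))
        }
    }
    rec(vec, character(0))
    hit / total
}

## direct per-sample phenotype tally (oracle for cohortPhenotypeTable)
phenotype_tally_oracle <- function(calls, strata, stratum, label) {
    ph <- vapply(calls, function(x) x@phenotype, character(1))
    sum(ph == label & strata == stratum) / sum(strata == stratum) * 100
}

## pair phased haplotypes into individuals while avoiding the
## phase-ambiguous double-heterozygote configuration, so that the revealed
## phase is fully identifiable from the genotypes
pair_identifiable <- function(haps) {
    tab <- table(factor(haps, levels = c("AB", "Ab", "aB", "ab")))
    out <- list()
    take <- function(h) { tab[h] <<- tab[h] - 1L; h }
    while (sum(tab) >= 2) {
        h1 <- take(names(tab)[which.max(tab)])
        ## partner must not complement h1 at both loci
        ok <- names(tab)[tab > 0]
        bad <- c(AB = "ab", ab = "AB", Ab = "aB", aB = "Ab")[h1]
        ok <- setdiff(ok, bad)
        if (!length(ok)) break
        h2 <- take(ok[which.max(tab[ok])])
        out[[length(out) + 1L]] <- c(h1, h2)
    }
    out
}

make_obs <- function(gene, het = character(), hom = character(), ...) {
    calls <- NULL
    if (length(het) || length(hom))
        calls <- data.frame(label = c(hom, het),
                            zygosity = c(rep("hom", length(hom)),
                                         rep("het", length(het))),
                            stringsAsFactors = FALSE)
    observedGenotype("t", gene, calls, ...)
}

pair_names <- function(pair) vapply(pair, function(r) r$name, character(1))

primary_or_alt_matches <- function(call, truthPair) {
    target <- paste(truthPair, collapse = "/")
    cand <- c(paste(call@primary, collapse = "/"),
              vapply(call@alternatives, paste, character(1),
                     collapse = "/"))
    target %in% cand
}
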