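## Cohort statistics: allele frequencies, count reconstruction from printed
## frequency tables, functional-class breakdowns, exact HWE and Fisher
## tests, and platform concordance.

#' Construct a CohortTable
#'
#' @param frequencies numeric matrix of percent allele frequencies,
#'   alleles in rows, strata in columns.
#' @param denominators named numeric vector: alleles identified (the
#'   frequency denominator) per stratum.
#' @param gene gene name.
#' @param phenotypeBlock optional phenotype percentage matrix.
#' @return a \code{\linkS4class{CohortTable}}.
#' @export
cohortTable <- function(frequencies, denominators, gene,
                        phenotypeBlock = NULL) {
    if (is.null(phenotypeBlock))
        phenotypeBlock <- matrix(numeric(), nrow = 0L, ncol = 0L)
    new("CohortTable", gene = gene, frequencies = frequencies,
        denominators = denominators[colnames(frequencies)],
        phenotypeBlock = phenotypeBlock)
}

#' Stratified allele frequency table from diplotype calls
#'
#' Counts the two primary alleles of every successfully called sample and
#' reports percent frequencies per stratum.  Samples whose phenotype is
#' \code{failure} or \code{no_call} are excluded from the denominators
#' (so the denominator is "alleles identified", twice the number of
#' successful samples, not twice the cohort size).
#'
#' @param calls list of \code{\linkS4class{DiplotypeCall}} objects (one
#'   gene).
#' @param strata character vector assigning each call to a stratum.
#' @return a \code{\linkS4class{CohortTable}}.
#' @export
alleleFrequencyTable <- function(calls, strata) {
    stopifnot(length(calls) > 0L, length(calls) == length(strata))
    gene <- calls[[1]]@gene
    ok <- vapply(calls, function(cc)
        !cc@phenotype %in% c("failure", "no_call"), logical(1))
    if (!any(ok)) stop("no successfully called samples")
    alleles <- unlist(lapply(calls[ok], function(cc) cc@primary))
    st2 <- rep(strata[ok], each = 2L)
    lv <- unique(strata[ok])
    tab <- table(factor(alleles, levels = sort(unique(alleles))),
                 factor(st2, levels = lv))
    den <- colSums(tab)
    keep <- den > 0
    tab <- tab[, keep, drop = FALSE]; den <- den[keep]
    fr <- sweep(tab, 2L, den, "/") * 100
    m <- matrix(as.numeric(fr), nrow = nrow(fr), dimnames = dimnames(fr))
    cohortTable(m, stats::setNames(as.numeric(den), colnames(m)), gene)
}

#' Reconstruct integer allele counts from a printed frequency table
#'
#' Inverts percent frequencies to counts using half-up rounding:
#' \code{count = floor(freq/100 * denominator + 0.5)}.  This reproduces
#' printed tallies such as a 10.7\% allele among 140 identified alleles
#' being 15 occurrences.
#'
#' @param table a \code{\linkS4class{CohortTable}}.
#' @return integer matrix of counts, same dimensions as the frequency
#'   block.
#' @export
reconstructCounts <- function(table) {
    stopifnot(is(table, "CohortTable"))
    den <- table@denominators
    if (anyNA(den)) stop("missing denominator(s)")
    fr <- table@frequencies
    cnt <- floor(sweep(fr / 100, 2L, den, "*") + 0.5)
    slack <- abs(colSums(cnt) - den)
    if (any(slack > 3))
        warning("reconstructed totals deviate from denominators by more ",
                "than 3 in: ",
                paste(colnames(fr)[slack > 3], collapse = ", "))
    storage.mode(cnt) <- "integer"
    cnt
}

#' Functional-class breakdown of allele counts
#'
#' Aggregates allele counts by activity class.  Unknown-class alleles are
#' pooled with the normal class (they score 1.0 by default) but their
#' count is reported separately in the \code{unknown_pooled} attribute.
#'
#' @param counts named integer vector of total allele counts, or a count
#'   matrix with allele rownames (summed across columns).
#' @param catalog an \code{AlleleCatalog}.
#' @param gene gene name.
#' @param total denominator for the percentages: the number of alleles
#'   identified.  Defaults to \code{sum(counts)}; pass the printed
#'   denominator when the counts come from a rounded frequency table (the
#'   reconstructed counts may then fall a few alleles short of it).
#' @return \code{data.frame} with columns \code{class} (absent, decreased,
#'   normal, increased), \code{count} and \code{percent}; attributes
#'   \code{total} and \code{unknown_pooled}.
#' @export
functionalClassBreakdown <- function(counts, catalog, gene,
                                     total = NULL) {
    if (is.matrix(counts)) {
        rs <- rowSums(counts)
        counts <- stats::setNames(as.integer(round(rs)), rownames(counts))
    }
    counts <- counts[counts > 0]
    cls <- vapply(names(counts), function(nm) {
        al <- catalog@alleles
        i <- which(al$gene == gene & al$name == nm)
        if (length(i) != 1L)
            stop("allele '", nm, "' absent from catalog for ", gene)
        al$activityClass[i]
    }, character(1))
    exact <- is.null(total)
    if (exact) total <- sum(counts)
    agg <- function(k) as.integer(sum(counts[cls %in% k]))
    unknown <- agg("unknown")
    out <- data.frame(
        class = c("absent", "decreased", "normal", "increased"),
        count = c(agg("absent"), agg("decreased"),
                  agg(c("normal", "unknown")), agg("increased")),
        stringsAsFactors = FALSE)
    out$percent <- out$count / total * 100
    stopifnot(abs(sum(out$count) - total) <= 5)
    if (exact) stopifnot(abs(sum(out$percent) - 100) <= 0.2)
    attr(out, "total") <- total
    attr(out, "unknown_pooled") <- unknown
    out
}

## log-probability of a genotype configuration conditional on allele counts
.hwe_log_prob <- function(counts, alleles) {
    het <- sum(counts[vapply(strsplit(names(counts), "/", fixed = TRUE),
                             function(p) p[1] != p[2], logical(1))])
    lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) + het * log(2)
}

#' Exact / Monte Carlo Hardy-Weinberg equilibrium test
#'
#' Tests genotype counts for deviation from Hardy-Weinberg equilibrium
#' conditional on the observed allele counts.  With two alleles the test
#' is exact: every possible heterozygote count is enumerated and the
#' two-sided p-value is the probability-ordered sum of configurations no
#' more likely than the observed one.  With more than two alleles the
#' null is sampled by seeded Monte Carlo permutation of the allele
#' vector, using the conditional probability of the genotype table as the
#' ordering statistic: \code{p = (1 + #\{T_sim <= T_obs\}) /
#' (1 + nPermutations)}.  Monomorphic data return p = 1.
#'
#' @param genotypeCounts named non-negative integer vector; names are
#'   diplotypes like \code{"*1/*2"} (allele order within a name is
#'   irrelevant).
#' @param seed integer seed for the Monte Carlo branch.
#' @param nPermutations number of Monte Carlo permutations (multi-allelic
#'   case only).
#' @return the p-value.
#' @examples
#' hweExactTest(c("A/A" = 3, "A/a" = 4, "a/a" = 3))
#' @export
hweExactTest <- function(genotypeCounts, seed = 1L, nPermutations = 1e5) {
    gc <- genotypeCounts[genotypeCounts > 0]
    if (length(gc) == 0L || sum(gc) == 0L) stop("zero samples")
    parts <- strsplit(names(gc), "/", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("genotype names must be 'a/b' pairs")
    ## canonicalise names so "b/a" and "a/b" pool
    canon <- vapply(parts, function(p) paste(sort(p), collapse = "/"),
                    character(1))
    gc <- tapply(gc, canon, sum)
    parts <- strsplit(names(gc), "/", fixed = TRUE)
    alleles <- sort(unique(unlist(parts)))
    if (length(alleles) == 1L) return(1.0)
    if (length(alleles) == 2L) return(.hwe_exact_biallelic(gc, parts, alleles))
    .hwe_mc(gc, parts, alleles, seed, nPermutations)
}

.hwe_exact_biallelic <- function(gc, parts, alleles) {
    a <- alleles[1]; b <- alleles[2]
    n <- sum(gc)
    cnt <- function(g) if (g %in% names(gc)) unname(gc[[g]]) else 0
    nAA <- cnt(paste(a, a, sep = "/"))
    nAB <- cnt(paste(sort(c(a, b)), collapse = "/"))
    nBB <- cnt(paste(b, b, sep = "/"))
    nA <- 2L * nAA + nAB
    ## feasible heterozygote counts share nA's parity
    hs <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
    logp <- vapply(hs, function(h) {
        aa <- (nA - h) / 2; bb <- n - aa - h
        lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
            h * log(2)
    }, numeric(1))
    p <- exp(logp - max(logp)); p <- p / sum(p)
    obs <- p[hs == nAB]
    min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

.hwe_mc <- function(gc, parts, alleles, seed, nPermutations) {
    set.seed(as.integer(seed))
    vec <- unlist(mapply(function(p, k) rep(p, k), parts, gc,
                         SIMPLIFY = FALSE))
    n <- sum(gc)
    odd <- seq(1L, 2L * n, by = 2L)
    t_obs <- .hwe_log_prob(gc, alleles)
    hits <- 0L
    for (i in seq_len(nPermutations)) {
        perm <- sample(vec)
        a1 <- perm[odd]; a2 <- perm[odd + 1L]
        g <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
        tg <- table(g)
        t_sim <- .hwe_log_prob(stats::setNames(as.numeric(tg), names(tg)),
                               alleles)
        if (t_sim <= t_obs + 1e-7) hits <- hits + 1L
    }
    (1 + hits) / (1 + nPermutations)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities (margins fixed) of every table no
#' more probable than the observed one, with a small relative tolerance
#' guard against floating-point ties.
#'
#' @param a,b,c,d non-negative integer cell counts (row-wise), or a 2x2
#'   matrix passed as \code{a}.
#' @return the two-sided p-value.
#' @examples
#' fisherExact2x2(5, 0, 0, 5)  # 2 / choose(10, 5)
#' @export
fisherExact2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) { b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1] }
    cells <- c(a, b, c, d)
    if (any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    if (sum(cells) == 0) stop("all-zero table")
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    xs <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(xs, r1, r2, c1)
    obs <- probs[xs == a]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

## canonical call table from either a list of DiplotypeCall or a data.frame
.asCallTable <- function(calls) {
    if (is.data.frame(calls)) {
        stopifnot(all(c("sample", "allele1", "allele2") %in% names(calls)))
        if (is.null(calls$status)) calls$status <- "ok"
        return(calls[, c("sample", "allele1", "allele2", "status")])
    }
    data.frame(
        sample = vapply(calls, function(cc) cc@sampleId, character(1)),
        allele1 = vapply(calls, function(cc) cc@primary[1], character(1)),
        allele2 = vapply(calls, function(cc) cc@primary[2], character(1)),
        status = vapply(calls, function(cc)
            if (cc@phenotype %in% c("failure", "no_call")) cc@phenotype
            else "ok", character(1)),
        stringsAsFactors = FALSE)
}

#' Concordance between two genotyping platforms' call sets
#'
#' Compares two call sets over the same samples: per-allele Fisher's exact
#' tests of allele counts against the total identified on each platform, a
#' per-sample diplotype agreement rate, and a miscall matrix tallying
#' which allele on side A was replaced by which on side B.  Samples failed
#' or uncalled on either side are excluded from the comparison and tallied.
#'
#' @param callsA,callsB lists of \code{DiplotypeCall} objects or
#'   data.frames with columns \code{sample}, \code{allele1},
#'   \code{allele2}, optional \code{status}.  Side A is conventionally
#'   the reference/truth platform.
#' @return list with elements \code{perAllele} (data.frame allele, countA,
#'   countB, p), \code{agreement} (proportion), \code{nCompared},
#'   \code{excluded} (named counts), \code{miscallMatrix} (matrix, rows =
#'   side-A allele, columns = side-B allele).
#' @export
platformConcordance <- function(callsA, callsB) {
    ta <- .asCallTable(callsA); tb <- .asCallTable(callsB)
    common <- intersect(ta$sample, tb$sample)
    if (length(common) == 0L)
        stop("call sets share no samples (disjoint sample sets)")
    ta <- ta[match(common, ta$sample), ]
    tb <- tb[match(common, tb$sample), ]
    okA <- ta$status == "ok"; okB <- tb$status == "ok"
    use <- okA & okB
    excluded <- c(failedA = sum(!okA), failedB = sum(!okB & okA))
    if (!any(use)) stop("no samples successfully called on both platforms")
    ta <- ta[use, ]; tb <- tb[use, ]
    n2 <- 2L * nrow(ta)
    aA <- c(ta$allele1, ta$allele2); aB <- c(tb$allele1, tb$allele2)
    alleles <- sort(unique(c(aA, aB)))
    per <- do.call(rbind, lapply(alleles, function(al) {
        ca <- sum(aA == al); cb <- sum(aB == al)
        p <- if (ca + cb == 0) 1.0 else
            fisherExact2x2(ca, n2 - ca, cb, n2 - cb)
        data.frame(allele = al, countA = ca, countB = cb, p = p,
                   stringsAsFactors = FALSE)
    }))
    sortPair <- function(a1, a2) {
        o <- order(.starNumber(c(a1, a2)), c(a1, a2))
        c(a1, a2)[o]
    }
    agree <- logical(nrow(ta))
    mm <- matrix(0L, length(alleles), length(alleles),
                 dimnames = list(truth = alleles, called = alleles))
    for (i in seq_len(nrow(ta))) {
        pa <- sortPair(ta$allele1[i], ta$allele2[i])
        pb <- sortPair(tb$allele1[i], tb$allele2[i])
        agree[i] <- identical(pa, pb)
        if (!agree[i]) {
            ## multiset difference, then positional pairing of the leftovers
            for (al in intersect(pa, pb)) {
                k <- min(sum(pa == al), sum(pb == al))
                if (k > 0) {
                    pa <- pa[-which(pa == al)[seq_len(k)]]
                    pb <- pb[-which(pb == al)[seq_len(k)]]
                }
            }
            for (j in seq_along(pa))
                mm[pa[j], pb[j]] <- mm[pa[j], pb[j]] + 1L
        }
    }
    list(perAllele = per, agreement = mean(agree), nCompared = nrow(ta),
         excluded = excluded, miscallMatrix = mm)
}
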