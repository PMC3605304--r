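## Pairwise linkage disequilibrium for two biallelic loci, from phased
## haplotypes or from unphased genotypes via EM haplotype-frequency
## estimation.

#' Pairwise linkage disequilibrium between two biallelic loci
#'
#' Computes D, D' and r-squared for two biallelic loci.  With phased input
#' the AB haplotype frequency is counted directly.  With unphased
#' genotypes the double-heterozygote phase is resolved by
#' expectation-maximisation over the four haplotype frequencies
#' (convergence tolerance 1e-8 on the haplotype frequencies, at most 1000
#' iterations).  Definitions: \code{D = pAB - pA*pB};
#' \code{D' = D / Dmax} where \code{Dmax = min(pA*pb, pa*pB)} for positive
#' D and \code{min(pA*pB, pa*pb)} for negative D;
#' \code{r2 = D^2 / (pA*pa*pB*pb)}.  A monomorphic locus leaves LD
#' undefined: the result is flagged and the statistics are \code{NA}.
#'
#' @param x for \code{phased = TRUE} a matrix with one row per haplotype
#'   (2 per individual) and two columns of 0/1 allele codes (1 = the
#'   counted allele); for \code{phased = FALSE} a matrix with one row per
#'   individual and two columns of 0/1/2 allele dosages.
#' @param phased logical.
#' @param tol,maxIter EM convergence controls.
#' @return list with \code{D}, \code{Dprime}, \code{r2}, \code{pA},
#'   \code{pB}, \code{pAB}, \code{defined} (logical), and
#'   \code{iterations} (0 for phased input).
#' @examples
#' hap <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))  # perfect coupling
#' ldPairwise(hap, phased = TRUE)$Dprime       # 1
#' @export
ldPairwise <- function(x, phased = FALSE, tol = 1e-8, maxIter = 1000L) {
    x <- as.matrix(x)
    stopifnot(ncol(x) == 2L, nrow(x) > 0L)
    if (phased) {
        stopifnot(all(x %in% 0:1))
        pAB <- mean(x[, 1] == 1 & x[, 2] == 1)
        pA <- mean(x[, 1]); pB <- mean(x[, 2])
        iters <- 0L
    } else {
        stopifnot(all(x %in% 0:2))
        n <- nrow(x)
        pA <- mean(x[, 1]) / 2; pB <- mean(x[, 2]) / 2
        if (pA %in% c(0, 1) || pB %in% c(0, 1))
            return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                        pA = pA, pB = pB, pAB = NA_real_, defined = FALSE,
                        iterations = 0L))
        ## only the double-heterozygote cell is phase-ambiguous
        nDH <- sum(x[, 1] == 1 & x[, 2] == 1)
        det <- .determinate_hap_counts(x)
        pAB <- pA * pB   # EM start: linkage equilibrium
        iters <- 0L
        repeat {
            iters <- iters + 1L
            pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
            num <- pAB * pab
            den <- num + pAb * paB
            w <- if (den > 0) num / den else 0.5
            pAB_new <- (det[["AB"]] + w * nDH) / (2 * n)
            if (abs(pAB_new - pAB) < tol || iters >= maxIter) {
                pAB <- pAB_new; break
            }
            pAB <- pAB_new
        }
    }
    pa <- 1 - pA; pb <- 1 - pB
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                    pA = pA, pB = pB, pAB = pAB, defined = FALSE,
                    iterations = iters))
    D <- pAB - pA * pB
    Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
    Dp <- if (Dmax > 0) D / Dmax else 0
    r2 <- D^2 / (pA * pa * pB * pb)
    list(D = D, Dprime = Dp, r2 = r2, pA = pA, pB = pB, pAB = pAB,
         defined = TRUE, iterations = iters)
}

## haplotype counts that are fully determined without phase information:
## every individual except the double heterozygote contributes known
## haplotypes; the double het contributes one haplotype to AB/ab or Ab/aB
## with unknown phase (handled by EM).
.determinate_hap_counts <- function(x) {
    counts <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
    for (i in seq_len(nrow(x))) {
        gA <- x[i, 1]; gB <- x[i, 2]
        if (gA == 1 && gB == 1) next  # double het: ambiguous
        ## decompose into two haplotypes
        a1 <- c(gA >= 1, gA == 2); b1 <- c(gB >= 1, gB == 2)
        for (k in 1:2) {
            key <- paste0(if (a1[k]) "A" else "a", if (b1[k]) "B" else "b")
            counts[key] <- counts[key] + 1
        }
    }
    counts
}
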