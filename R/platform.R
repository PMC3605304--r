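## Parametrised genotyping-platform error models and their application to
## ground-truth cohorts.

#' Error-free platform profile
#'
#' The identity profile: no miscalls, no deletion dropout, no failures,
#' no no-calls.  Applying it to a truth cohort reproduces the truth
#' exactly.
#'
#' @return a \code{\linkS4class{PlatformProfile}}.
#' @export
errorFreeProfile <- function() {
    new("PlatformProfile", name = "error-free",
        miscallMap = data.frame(gene = character(), from = character(),
                                to = character(), prob = numeric(),
                                stringsAsFactors = FALSE),
        deletionDropoutProb = 0, failureProb = 0, noCallProb = 0,
        uncoveredAlleles = character())
}

#' Array-platform (AmpliChip-style) error profile
#'
#' Emulates the documented error modes of the array genotyping platform
#' relative to the comprehensive platforms.  Alleles the array cannot
#' represent are miscalled deterministically (probability 1): CYP2D6
#' *45B and *46 to *41, *56B to *10, *59 to *2 or *22 (50/50), *33 and
#' *43 to *1, and the novel *4P/*84/*85/*86 to their nearest covered
#' backbone; CYP2C19 alleles beyond *1/*2/*3 are reported as wild type
#' *1, and the hybrid *2+*27 as *2.  Rate-based error modes are
#' estimates derived from the reported miscall tallies relative to
#' exposure counts, not measured per-allele rates: *2 to *41 (9 of ~24
#' exposures, 0.375), *1 to *41 (5 of ~72, 0.07), heterozygous *5
#' dropout (12/17, with the partner allele then reported homozygous).
#' Whole-sample failure probability 0.224 and no-call probability 0.04.
#' Every value is a plain slot and can be overridden.
#'
#' @param deletionDropoutProb,failureProb,noCallProb override the default
#'   rates.
#' @return a \code{\linkS4class{PlatformProfile}}.
#' @export
amplichipProfile <- function(deletionDropoutProb = 12 / 17,
                             failureProb = 0.224, noCallProb = 0.04) {
    mm <- rbind(
        data.frame(gene = "CYP2D6",
                   from = c("*45B", "*46", "*56B", "*59", "*59", "*33",
                            "*43", "*4P", "*84", "*85", "*86", "*2", "*1"),
                   to = c("*41", "*41", "*10", "*2", "*22", "*1", "*1",
                          "*4", "*2", "*2", "*1", "*41", "*41"),
                   prob = c(1, 1, 1, 0.5, 0.5, 1, 1, 1, 1, 1, 1, 0.375,
                            0.07),
                   stringsAsFactors = FALSE),
        data.frame(gene = "CYP2C19",
                   from = c("*9", "*15", "*17", "*27", "*28", "*2+*27"),
                   to = c("*1", "*1", "*1", "*1", "*1", "*2"),
                   prob = 1, stringsAsFactors = FALSE))
    new("PlatformProfile", name = "amplichip", miscallMap = mm,
        deletionDropoutProb = deletionDropoutProb,
        failureProb = failureProb, noCallProb = noCallProb,
        uncoveredAlleles = c("*45B", "*46", "*56B", "*59", "*33", "*43",
                             "*4P", "*84", "*85", "*86", "*9", "*15",
                             "*17", "*27", "*28", "*2+*27"))
}

.miscallOne <- function(allele, gene, profile) {
    mm <- profile@miscallMap
    rows <- mm[mm$gene == gene & mm$from == allele, , drop = FALSE]
    if (nrow(rows) == 0L) return(allele)
    u <- stats::runif(1)
    cum <- cumsum(rows$prob)
    i <- which(u <= cum)
    if (length(i) == 0L) allele else rows$to[i[1]]
}

#' Corrupt a truth cohort with a platform error model
#'
#' Applies, in order: whole-sample failure and no-call draws, per-haplotype
#' allele miscalls, and heterozygous-deletion dropout (a (*X, *5)
#' diplotype reported as (*X, *X)).  The error-free profile is the
#' identity.  Observed variant-level calls and CNV flags are regenerated
#' from the observed diplotypes so the observed cohort can be pushed
#' through the caller exactly like a real call set.
#'
#' @param truth result of \code{\link{simulateTruth}}.
#' @param profile a \code{\linkS4class{PlatformProfile}}.
#' @param seed integer random seed.
#' @param catalog allele catalog.
#' @return a list like \code{\link{simulateTruth}}'s, with
#'   \code{observed} (data.frame \code{sample}, \code{stratum},
#'   \code{gene}, \code{allele1}, \code{allele2}, \code{status}) and
#'   regenerated \code{observations}; failed / no-call samples carry
#'   status \code{"failure"} / \code{"no_call"} and no observation.
#' @export
applyPlatformModel <- function(truth, profile, seed,
                               catalog = builtinCatalog()) {
    stopifnot(is(profile, "PlatformProfile"))
    validObject(profile)
    set.seed(as.integer(seed))
    tr <- truth$truth
    gene <- truth$gene
    obs <- list()
    out <- tr
    for (i in seq_len(nrow(tr))) {
        id <- tr$sample[i]
        u <- stats::runif(1)
        if (u < profile@failureProb) {
            out$status[i] <- "failure"
            out$allele1[i] <- NA_character_; out$allele2[i] <- NA_character_
            next
        }
        if (u < profile@failureProb + profile@noCallProb) {
            out$status[i] <- "no_call"
            out$allele1[i] <- NA_character_; out$allele2[i] <- NA_character_
            next
        }
        a <- c(tr$allele1[i], tr$allele2[i])
        a <- vapply(a, .miscallOne, character(1), gene = gene,
                    profile = profile)
        if (sum(a == "*5") == 1L &&
            stats::runif(1) < profile@deletionDropoutProb) {
            partner <- a[a != "*5"]
            a <- c(partner, partner)
        }
        o <- order(.starNumber(a), a)
        out$allele1[i] <- a[o[1]]; out$allele2[i] <- a[o[2]]
        obs[[id]] <- .observationFor(id, gene, a[o[1]], a[o[2]], catalog)
    }
    list(truth = truth$truth, observed = out, observations = obs,
         gene = gene, seed = as.integer(seed))
}
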