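## Synthetic cohort generation: stratified Hardy-Weinberg sampling from
## star-allele frequency maps, with CNV and hybrid haplotypes, plus
## regeneration of the variant-level observations a caller would see.

## Default per-stratum allele frequencies (percent, as printed in the
## comprehensive-platform columns of the cohort frequency tables:
## gene re-sequencing for CYP2D6, PCR-RFLP for CYP2C19).  Strata are the
## four population groups with sample sizes 70/10/10/10.  Each vector is
## renormalised to sum to 1 (printed percentages carry rounding).  For
## CYP2C19 the hybrid *2+*27 haplotype (carried by 3 Black African and 1
## Indian chromosome) is split out of the printed *2 frequency.
.DEFAULT_STRATA <- c(BlackAfrican = 70L, Caucasian = 10L, Coloured = 10L,
                     Indian = 10L)

.DEFAULT_FREQ <- list(
    CYP2D6 = list(
        BlackAfrican = c("*1" = 25.7, "*2" = 8.6, "*5" = 10.7, "*10" = 5.7,
                         "*17" = 25.7, "*29" = 4.3, "*40" = 3.6,
                         "*41" = 0.7, "*43" = 0.7, "*45B" = 5.7,
                         "*46" = 0.7, "*56B" = 0.7, "*84" = 0.7,
                         "*85" = 0.7, "*2xN" = 0.7, "*4xN" = 2.9),
        Caucasian = c("*1" = 30, "*2" = 15, "*4" = 20, "*5" = 5,
                      "*10" = 5, "*33" = 5, "*35" = 5, "*41" = 15),
        Coloured = c("*1" = 30, "*2" = 15, "*4" = 15, "*5" = 5, "*10" = 5,
                     "*17" = 10, "*29" = 5, "*41" = 5, "*43" = 5,
                     "*59" = 0.5),
        Indian = c("*1" = 45, "*2" = 30, "*22" = 5, "*41" = 10, "*43" = 5,
                   "*86" = 5)),
    CYP2C19 = list(
        BlackAfrican = c("*1" = 32.1, "*2" = 15.757, "*2+*27" = 2.143,
                         "*9" = 3.6, "*15" = 5.7, "*17" = 16.4,
                         "*27" = 24.3),
        Caucasian = c("*1" = 70, "*2" = 5, "*17" = 25),
        Coloured = c("*1" = 40, "*2" = 35, "*15" = 10, "*27" = 15),
        Indian = c("*1" = 40, "*2" = 30, "*2+*27" = 5, "*17" = 5,
                   "*27" = 20)))

#' Construct a SimulationConfig
#'
#' @param gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @param strataSizes named integer vector of samples per stratum.
#' @param frequencies named list (one element per stratum) of named
#'   numeric allele-frequency vectors; they are renormalised to sum to 1.
#' @param catalog catalog used to validate allele names.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(gene, strataSizes, frequencies,
                             catalog = builtinCatalog()) {
    known <- alleleNames(catalog, gene)
    for (s in names(frequencies)) {
        bad <- setdiff(names(frequencies[[s]]), known)
        if (length(bad))
            stop("frequency map for stratum '", s, "' names allele(s) ",
                 "missing from the catalog: ", paste(bad, collapse = ", "))
        frequencies[[s]] <- frequencies[[s]] / sum(frequencies[[s]])
    }
    new("SimulationConfig", gene = gene,
        strataSizes = stats::setNames(as.integer(strataSizes),
                                      names(strataSizes)),
        frequencies = frequencies)
}

#' Default stratified cohort configuration
#'
#' The default conditions the simulator emulates: a 100-sample cohort of
#' 70 Black African, 10 Caucasian, 10 Coloured and 10 Indian individuals,
#' with per-stratum star-allele frequencies transcribed from the
#' comprehensive-platform columns of the study-population frequency
#' tables (gene re-sequencing for CYP2D6; PCR-RFLP for CYP2C19, with the
#' hybrid *2+*27 haplotype split out of *2).
#'
#' @param gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @param strataSizes named integer vector; defaults to 70/10/10/10.
#' @param catalog allele catalog.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
defaultCohortConfig <- function(gene = c("CYP2D6", "CYP2C19"),
                                strataSizes = .DEFAULT_STRATA,
                                catalog = builtinCatalog()) {
    gene <- match.arg(gene)
    simulationConfig(gene, strataSizes, .DEFAULT_FREQ[[gene]], catalog)
}

## per-haplotype variant labels: xN alleles carry their base allele's
## variants; exon-9 conversion products carry their base's variants plus
## the conversion flag (handled at the observation level).
.hapVariants <- function(catalog, gene, name) {
    a <- getAllele(catalog, gene, name)
    if (a$cnvMultiplier >= 2L && !is.na(a$baseAllele))
        a <- getAllele(catalog, gene, a$baseAllele)
    conv <- a$annotations$conversionOf
    if (!is.null(conv)) a <- getAllele(catalog, gene, conv)
    union(a$keyVariants, a$backboneVariants)
}

.isConversionAllele <- function(catalog, gene, name) {
    a <- getAllele(catalog, gene, name)
    !is.null(a$annotations$conversionOf)
}

## reconstruct the ObservedGenotype a perfect assay would emit for a truth
## diplotype
.observationFor <- function(sampleId, gene, a1, a2, catalog) {
    v1 <- if (a1 == "*5") character() else .hapVariants(catalog, gene, a1)
    v2 <- if (a2 == "*5") character() else .hapVariants(catalog, gene, a2)
    shared <- intersect(v1, v2)
    dels <- sum(c(a1, a2) == "*5")
    ## with one deletion the remaining variants sit on a single copy and
    ## are reported homozygous by sequencing assays
    if (dels == 1L) { shared <- union(v1, v2) }
    hets <- setdiff(union(v1, v2), shared)
    labs <- c(shared, hets)
    calls <- if (length(labs))
        data.frame(label = labs,
                   zygosity = c(rep("hom", length(shared)),
                                rep("het", length(hets))),
                   phaseSet = NA_character_, stringsAsFactors = FALSE)
    else NULL
    xn <- grepl("xN$", c(a1, a2))
    hint <- if (any(xn)) unique(sub("xN$", "", c(a1, a2)[xn]))
            else NA_character_
    conv <- any(vapply(c(a1, a2), function(nm)
        nm != "*5" && .isConversionAllele(catalog, gene, nm), logical(1)))
    observedGenotype(sampleId, gene, calls, deletionCopies = dels,
                     duplicationPresent = any(xn),
                     duplicatedAlleleHint = hint, exon9Conversion = conv)
}

#' Simulate a ground-truth cohort under Hardy-Weinberg equilibrium
#'
#' Within each stratum, every individual's two alleles are drawn
#' independently from the stratum allele-frequency map (Hardy-Weinberg
#' sampling).  Variant calls are derived from the catalog key and
#' backbone variants of the drawn alleles; *5 draws set the deletion
#' assay flags and xN draws the duplication flags.  Reproducible for a
#' fixed seed.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param seed integer random seed.
#' @param catalog allele catalog.
#' @param withObservations build the per-sample
#'   \code{\linkS4class{ObservedGenotype}} objects (default); set
#'   \code{FALSE} when only the truth diplotypes are needed (e.g. for
#'   large calibration draws).
#' @return a list with elements \code{truth} (data.frame: \code{sample},
#'   \code{stratum}, \code{gene}, \code{allele1}, \code{allele2},
#'   \code{status}), \code{observations} (named list of
#'   \code{\linkS4class{ObservedGenotype}}), \code{gene}, \code{seed}.
#' @examples
#' cfg <- defaultCohortConfig("CYP2C19")
#' sim <- simulateTruth(cfg, seed = 42)
#' head(sim$truth)
#' @export
simulateTruth <- function(config, seed, catalog = builtinCatalog(),
                          withObservations = TRUE) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(as.integer(seed))
    gene <- config@gene
    strata <- rep(names(config@strataSizes), config@strataSizes)
    ntot <- length(strata)
    a1 <- character(ntot); a2 <- character(ntot)
    idx <- 0L
    for (s in names(config@strataSizes)) {
        n <- config@strataSizes[[s]]
        f <- config@frequencies[[s]]
        draw <- matrix(sample(names(f), 2L * n, replace = TRUE, prob = f),
                       ncol = 2L)
        ## normalise pair order: lower star number (then name) first
        num <- matrix(.starNumber(draw), ncol = 2L)
        swap <- num[, 1] > num[, 2] |
            (num[, 1] == num[, 2] & draw[, 1] > draw[, 2])
        first <- ifelse(swap, draw[, 2], draw[, 1])
        second <- ifelse(swap, draw[, 1], draw[, 2])
        a1[idx + seq_len(n)] <- first
        a2[idx + seq_len(n)] <- second
        idx <- idx + n
    }
    ids <- sprintf("S%04d", seq_len(ntot))
    truth <- data.frame(sample = ids, stratum = strata, gene = gene,
                        allele1 = a1, allele2 = a2, status = "ok",
                        stringsAsFactors = FALSE)
    obs <- list()
    if (withObservations) {
        ## one template per distinct diplotype; clones differ only in id
        cache <- list()
        for (i in seq_len(ntot)) {
            key <- paste(a1[i], a2[i])
            tmpl <- cache[[key]]
            if (is.null(tmpl)) {
                tmpl <- .observationFor(ids[i], gene, a1[i], a2[i], catalog)
                cache[[key]] <- tmpl
            }
            tmpl@sampleId <- ids[i]
            obs[[ids[i]]] <- tmpl
        }
    }
    list(truth = truth, observations = obs, gene = gene,
         seed = as.integer(seed))
}
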