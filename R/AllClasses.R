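#' @import methods
NULL

.GENES <- c("CYP2D6", "CYP2C19")
.ACTIVITY_CLASSES <- c(increased = 2.0, normal = 1.0, decreased = 0.5,
                       absent = 0.0, unknown = 1.0)
.PHENOTYPES <- c("PM", "IM", "EM", "UM", "unknown", "no_call", "failure")

#' AlleleCatalog: star-allele definitions and activity assignments
#'
#' Container for the star-allele (named haplotype) definitions of one or
#' more pharmacogenes.  Each allele row carries its allele-defining ("key")
#' variants, any non-defining backbone variants it is known to carry, an
#' activity class (increased / normal / decreased / absent / unknown) with
#' the corresponding numeric activity value, a copy-number multiplier
#' (0 for the whole-gene deletion allele *5, 2 for xN duplication alleles,
#' 1 otherwise) and free-form annotations.
#'
#' Validity requires: a reference allele *1 with an empty key-variant set
#' for every gene; unique allele names within a gene; pairwise-distinct key
#' sets among the sequence-defined (copy-number 1) alleles; numeric
#' activities in \{0, 0.5, 1, 2\}; *5 with empty variant sets and copy
#' number 0; and every variant label parseable with a non-zero position.
#'
#' @slot alleles a \code{data.frame} with columns \code{gene}, \code{name},
#'   \code{activityClass}, \code{activityValue}, \code{cnvMultiplier},
#'   \code{baseAllele} (for xN alleles), and list-columns
#'   \code{keyVariants}, \code{backboneVariants}, \code{annotations}.
#' @seealso \code{\link{builtinCatalog}}, \code{\link{loadCatalog}},
#'   \code{\link{activityOf}}
#' @export
setClass("AlleleCatalog", representation(alleles = "data.frame"))

setValidity("AlleleCatalog", function(object) {
    al <- object@alleles
    need <- c("gene", "name", "activityClass", "activityValue",
              "cnvMultiplier", "baseAllele", "keyVariants",
              "backboneVariants", "annotations")
    if (!all(need %in% names(al)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(al)), collapse = ", ")))
    if (nrow(al) == 0L) return("catalog contains no alleles")
    if (!all(al$gene %in% .GENES))
        return("unsupported gene name(s)")
    if (!all(al$activityClass %in% names(.ACTIVITY_CLASSES)))
        return("invalid activity class")
    if (!all(al$activityValue %in% c(0, 0.5, 1, 2)))
        return("numeric activity must be one of 0, 0.5, 1, 2")
    for (g in unique(al$gene)) {
        sub <- al[al$gene == g, ]
        if (anyDuplicated(sub$name))
            return(paste0("duplicate allele name(s) for ", g, ": ",
                          paste(unique(sub$name[duplicated(sub$name)]),
                                collapse = ", ")))
        ref <- sub[sub$name == "*1", ]
        if (nrow(ref) != 1L || length(ref$keyVariants[[1]]) != 0L)
            return(paste0(g, " must contain reference allele *1 with an ",
                          "empty key-variant set"))
        del <- sub[sub$name == "*5", ]
        if (nrow(del) == 1L &&
            (del$cnvMultiplier != 0L ||
             length(del$keyVariants[[1]]) != 0L ||
             length(del$backboneVariants[[1]]) != 0L))
            return("*5 must have empty variant sets and copy number 0")
        seqdef <- sub[sub$cnvMultiplier == 1L, ]
        keys <- lapply(seqdef$keyVariants, function(k) sort(unique(k)))
        sig <- vapply(keys, paste, character(1), collapse = "|")
        if (anyDuplicated(sig))
            return(paste0("alleles of ", g, " share identical key-variant ",
                          "sets: ",
                          paste(seqdef$name[sig %in% sig[duplicated(sig)]],
                                collapse = ", ")))
    }
    labs <- unique(unlist(c(al$keyVariants, al$backboneVariants)))
    if (length(labs)) {
        parsed <- tryCatch(parseVariantLabel(labs), error = identity)
        if (inherits(parsed, "error"))
            return(conditionMessage(parsed))
        if (!identical(parsed$label, labs))
            return("variant labels do not round-trip")
    }
    xn <- al[al$cnvMultiplier >= 2L, ]
    if (nrow(xn) && any(is.na(xn$baseAllele)))
        return("xN alleles must reference a base allele name")
    TRUE
})

#' ObservedGenotype: one sample's per-gene variant observations
#'
#' Bundles the variant calls observed for one sample at one gene together
#' with the copy-number assay evidence (count of *5 deletion alleles from
#' the duplex long-range PCR, duplication presence and, when the
#' duplication-specific product was sequenced, the duplicated allele) and
#' the exon-9 gene-conversion assay flag.
#'
#' @slot sampleId character scalar.
#' @slot gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @slot calls \code{data.frame} with columns \code{label} (variant label),
#'   \code{zygosity} (\code{"het"} or \code{"hom"}) and \code{phaseSet}
#'   (identifier grouping calls known to lie on one molecule; \code{NA} if
#'   unphased).
#' @slot deletionCopies integer 0--2; if 2 the call set must be empty.
#' @slot duplicationPresent logical.
#' @slot duplicatedAlleleHint allele name(s) of the duplicated gene
#'   copy/copies as characterised by sequencing the duplication-specific
#'   product, or \code{NA} when uncharacterised.
#' @slot exon9Conversion logical; evidence of a CYP2D7 exon-9 conversion.
#' @export
setClass("ObservedGenotype",
         representation(sampleId = "character", gene = "character",
                        calls = "data.frame", deletionCopies = "integer",
                        duplicationPresent = "logical",
                        duplicatedAlleleHint = "character",
                        exon9Conversion = "logical"))

setValidity("ObservedGenotype", function(object) {
    if (length(object@gene) != 1L || !object@gene %in% .GENES)
        return("gene must be one of CYP2D6, CYP2C19")
    cl <- object@calls
    if (!all(c("label", "zygosity", "phaseSet") %in% names(cl)))
        return("calls needs columns label, zygosity, phaseSet")
    if (nrow(cl) && !all(cl$zygosity %in% c("het", "hom")))
        return("zygosity must be het or hom")
    if (nrow(cl) && any(cl$zygosity == "hom" & !is.na(cl$phaseSet)))
        return("hom calls have no phase ambiguity; phaseSet must be NA")
    if (nrow(cl) && anyDuplicated(cl$label))
        return("duplicate variant labels in calls")
    dc <- object@deletionCopies
    if (length(dc) != 1L || is.na(dc) || dc < 0L || dc > 2L)
        return("deletionCopies must be 0, 1 or 2")
    if (dc == 2L && nrow(cl) > 0L)
        return("deletionCopies = 2 implies an empty call set")
    TRUE
})

#' DiplotypeCall: assigned allele pair with score and phenotype
#'
#' Result of calling one sample at one gene: the primary diplotype
#' (normalised so the lower-numbered allele comes first), equally
#' consistent alternative explanations, the additive Activity Score, the
#' predicted metaboliser phenotype under the Activity-Score scheme (and
#' optionally the categorical array-rule scheme), any novel-allele
#' candidates, and diagnostic notes.
#'
#' @slot sampleId,gene identifiers.
#' @slot primary character vector of length 2 (allele names; novel
#'   candidates appear as \code{"novel(<backbone>+<extras>)"} labels).
#' @slot alternatives list of further consistent pairs.
#' @slot activityScore numeric Activity Score of the primary diplotype.
#' @slot phenotype one of PM, IM, EM, UM, unknown, no_call, failure.
#' @slot phenotypeAmplichip categorical-rule phenotype (\code{NA} when not
#'   requested); \code{ruleFired} records which rule row produced it.
#' @slot novelCandidates list of novel-allele candidate records.
#' @slot notes character vector of diagnostics.
#' @export
setClass("DiplotypeCall",
         representation(sampleId = "character", gene = "character",
                        primary = "character", alternatives = "list",
                        activityScore = "numeric", phenotype = "character",
                        phenotypeAmplichip = "character",
                        ruleFired = "character",
                        novelCandidates = "list", notes = "character"))

setValidity("DiplotypeCall", function(object) {
    if (length(object@primary) != 2L)
        return("primary must be an allele pair")
    if (!object@phenotype %in% .PHENOTYPES)
        return("invalid phenotype label")
    TRUE
})

#' NovelAlleleCandidate: an unexplained haplotype
#'
#' Produced when a haplotype's variants are not fully explained by any
#' catalog allele: the closest (maximal partial) match becomes the
#' backbone, the unexplained variants are recorded, and the candidate is
#' assigned activity 0.0 if the haplotype carries a known null-defining
#' variant (a key variant of an absent-class allele, e.g. the splice
#' defect 1846G>A), else the field-standard default of 1.0.
#'
#' @slot backbone closest matching catalog allele name.
#' @slot extraVariants character vector of unexplained variant labels.
#' @slot assignedActivity 0 or 1.
#' @slot rationale character scalar.
#' @export
setClass("NovelAlleleCandidate",
         representation(backbone = "character", extraVariants = "character",
                        assignedActivity = "numeric", rationale = "character"))

#' PlatformProfile: parametrised genotyping-platform error model
#'
#' Describes how a genotyping platform corrupts true diplotypes: a
#' per-haplotype miscall map (truth allele to called allele with a firing
#' probability; several rows may share a source allele provided their
#' probabilities sum to at most 1), the probability that a heterozygous
#' whole-gene deletion (*5) is missed so the partner allele is reported
#' homozygous, whole-sample assay failure and no-call probabilities, and
#' the set of alleles the platform cannot represent.
#'
#' @slot name profile name.
#' @slot miscallMap \code{data.frame} with columns \code{gene},
#'   \code{from}, \code{to}, \code{prob}.
#' @slot deletionDropoutProb,failureProb,noCallProb probabilities in [0,1].
#' @slot uncoveredAlleles character vector of allele names.
#' @seealso \code{\link{amplichipProfile}}, \code{\link{errorFreeProfile}}
#' @export
setClass("PlatformProfile",
         representation(name = "character", miscallMap = "data.frame",
                        deletionDropoutProb = "numeric",
                        failureProb = "numeric", noCallProb = "numeric",
                        uncoveredAlleles = "character"))

setValidity("PlatformProfile", function(object) {
    mm <- object@miscallMap
    if (!all(c("gene", "from", "to", "prob") %in% names(mm)))
        return("miscallMap needs columns gene, from, to, prob")
    p <- c(object@deletionDropoutProb, object@failureProb,
           object@noCallProb, if (nrow(mm)) mm$prob)
    if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
    if (nrow(mm)) {
        s <- tapply(mm$prob, paste(mm$gene, mm$from), sum)
        if (any(s > 1 + 1e-9))
            return("miscall probabilities for one source allele exceed 1")
    }
    TRUE
})

#' SimulationConfig: stratified cohort simulation parameters
#'
#' Defines a synthetic cohort: the gene, ordered strata with sample sizes,
#' and a per-stratum star-allele frequency map from which two alleles per
#' individual are drawn independently (Hardy-Weinberg sampling).
#'
#' @slot gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @slot strataSizes named integer vector (stratum label -> sample count).
#' @slot frequencies named list (per stratum) of named numeric allele
#'   frequency vectors, each summing to 1 within 1e-9.
#' @seealso \code{\link{defaultCohortConfig}}, \code{\link{simulateTruth}}
#' @export
setClass("SimulationConfig",
         representation(gene = "character", strataSizes = "integer",
                        frequencies = "list"))

setValidity("SimulationConfig", function(object) {
    if (length(object@gene) != 1L || !object@gene %in% .GENES)
        return("gene must be one of CYP2D6, CYP2C19")
    sz <- object@strataSizes
    if (is.null(names(sz)) || any(sz <= 0L))
        return("strataSizes must be a named vector of positive counts")
    fr <- object@frequencies
    if (!identical(sort(names(fr)), sort(names(sz))))
        return("frequencies must name exactly the configured strata")
    for (s in names(fr)) {
        f <- fr[[s]]
        if (is.null(names(f)) || any(f < 0))
            return(paste0("stratum '", s, "': frequencies must be a named ",
                          "non-negative vector"))
        if (abs(sum(f) - 1) > 1e-9)
            return(paste0("stratum '", s, "': frequencies must sum to 1 ",
                          "(got ", format(sum(f), digits = 12), ")"))
    }
    TRUE
})

#' CohortTable: stratified allele-frequency table with denominators
#'
#' Percent allele frequencies per stratum with the number of successfully
#' identified alleles (the denominator) per stratum, as printed in cohort
#' frequency tables.
#'
#' @slot gene gene name.
#' @slot frequencies numeric matrix (alleles x strata) of percentages.
#' @slot denominators named numeric vector of alleles identified per
#'   stratum.
#' @slot phenotypeBlock optional matrix of phenotype percentages
#'   (rows PM/IM/EM/UM/unknown/no_call/failure) or a 0-row matrix.
#' @export
setClass("CohortTable",
         representation(gene = "character", frequencies = "matrix",
                        denominators = "numeric", phenotypeBlock = "matrix"))

setValidity("CohortTable", function(object) {
    fr <- object@frequencies
    if (is.null(rownames(fr)) || is.null(colnames(fr)))
        return("frequencies must have allele rownames and stratum colnames")
    if (!identical(colnames(fr), names(object@denominators)))
        return("denominators must be named by the frequency table strata")
    if (any(object@denominators <= 0))
        return("denominators must be positive")
    tol <- 0.5 * nrow(fr)   # printed-rounding slack, 0.5 per allele row
    tot <- colSums(fr)
    if (any(abs(tot - 100) > tol))
        return("per-stratum frequencies must sum to 100 within rounding")
    TRUE
})

setMethod("show", "AlleleCatalog", function(object) {
    al <- object@alleles
    cat("AlleleCatalog with", nrow(al), "star alleles\n")
    for (g in unique(al$gene)) {
        sub <- al[al$gene == g, ]
        cat("  ", g, ": ", nrow(sub), " alleles (",
            paste(head(sub$name, 8), collapse = ", "),
            if (nrow(sub) > 8) ", ..." else "", ")\n", sep = "")
    }
})

setMethod("show", "ObservedGenotype", function(object) {
    cat("ObservedGenotype", object@sampleId, "/", object@gene, "\n")
    cat("  variant calls:", nrow(object@calls),
        " deletionCopies:", object@deletionCopies,
        " duplication:", object@duplicationPresent,
        " exon9conv:", object@exon9Conversion, "\n")
})

setMethod("show", "DiplotypeCall", function(object) {
    cat("DiplotypeCall ", object@sampleId, " ", object@gene, ": ",
        paste(object@primary, collapse = "/"),
        "  AS=", object@activityScore,
        "  phenotype=", object@phenotype, "\n", sep = "")
    if (length(object@alternatives))
        cat("  alternatives: ",
            paste(vapply(object@alternatives, paste, character(1),
                         collapse = "/"), collapse = "; "), "\n", sep = "")
})

setMethod("show", "PlatformProfile", function(object) {
    cat("PlatformProfile '", object@name, "': ", nrow(object@miscallMap),
        " miscall rules, deletion dropout ", object@deletionDropoutProb,
        ", failure ", object@failureProb, ", no-call ", object@noCallProb,
        "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig for", object@gene, "-",
        sum(object@strataSizes), "samples in",
        length(object@strataSizes), "strata\n")
    print(object@strataSizes)
})

setMethod("show", "CohortTable", function(object) {
    cat("CohortTable (", object@gene, "), ", nrow(object@frequencies),
        " alleles x ", ncol(object@frequencies), " strata\n", sep = "")
    print(round(object@frequencies, 1))
    cat("alleles identified (n):\n")
    print(object@denominators)
})
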