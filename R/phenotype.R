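## Activity Scores and metaboliser phenotype prediction under the additive
## Activity-Score thresholds and the categorical array-style rules.

#' Activity Score of a diplotype
#'
#' The Activity Score (AS) is the plain sum of the two alleles' numeric
#' activity values (increased 2.0, normal 1.0, decreased 0.5, absent 0.0,
#' unknown defaulting to 1.0; duplication alleles contribute twice their
#' base activity).  For example the CYP2C19 diplotype *2/*27 scores
#' 0 + 0.5 = 0.5 while *2+*27/*1 scores 0 + 1 = 1.0.
#'
#' @param pair character vector of two allele names (novel-candidate
#'   labels allowed when \code{novelActivities} supplies their values).
#' @param gene gene name.
#' @param catalog an \code{AlleleCatalog}.
#' @param novelActivities optional named numeric vector giving the
#'   assigned activity of novel-candidate labels.
#' @return numeric Activity Score.
#' @examples
#' cat2 <- builtinCatalog()
#' activityScore(c("*2", "*27"), "CYP2C19", cat2)     # 0.5
#' activityScore(c("*2+*27", "*1"), "CYP2C19", cat2)  # 1.0
#' @export
activityScore <- function(pair, gene, catalog, novelActivities = NULL) {
    stopifnot(length(pair) == 2L)
    sum(vapply(pair, function(nm) {
        if (!is.null(novelActivities) && nm %in% names(novelActivities))
            return(unname(novelActivities[nm]))
        activityOf(catalog, gene, nm)
    }, numeric(1)))
}

#' Classify an Activity Score into a metaboliser phenotype
#'
#' Thresholds: AS > 2.0 is ultra-rapid (UM); 1.5--2.0 extensive (EM);
#' 0.5--1.0 intermediate (IM); 0.0 poor (PM).  Scores are sums of
#' per-allele values in \{0, 0.5, 1, 2\} so every attainable score is a
#' non-negative multiple of 0.5 and no score falls strictly between 0 and
#' 0.5; anything else is a domain error.
#'
#' @param score numeric Activity Score.
#' @return one of \code{"PM"}, \code{"IM"}, \code{"EM"}, \code{"UM"}.
#' @examples
#' classifyActivityScore(0)    # "PM"
#' classifyActivityScore(1.5)  # "EM"
#' classifyActivityScore(2.5)  # "UM"
#' @export
classifyActivityScore <- function(score) {
    stopifnot(length(score) == 1L, is.numeric(score))
    if (is.na(score)) stop("Activity Score is NA")
    if (score < 0 || abs(score * 2 - round(score * 2)) > 1e-9)
        stop("Activity Score must be a non-negative multiple of 0.5, got ",
             score)
    if (score > 2 + 1e-9) "UM"
    else if (score >= 1.5 - 1e-9) "EM"
    else if (score >= 0.5 - 1e-9) "IM"
    else "PM"
}

## class / copy-count / value of an allele label for the categorical rules
.alleleInfo <- function(name, gene, catalog, novelActivities = NULL) {
    al <- catalog@alleles
    i <- which(al$gene == gene & al$name == name)
    if (length(i) == 1L)
        return(list(class = al$activityClass[i],
                    copies = max(al$cnvMultiplier[i], 0L),
                    value = al$activityValue[i]))
    if (grepl("xN$", name)) {
        base <- .alleleInfo(sub("xN$", "", name), gene, catalog)
        return(list(class = base$class, copies = 2L, value = 2 * base$value))
    }
    if (!is.null(novelActivities) && name %in% names(novelActivities)) {
        v <- unname(novelActivities[name])
        return(list(class = if (v == 0) "absent" else "unknown",
                    copies = 1L, value = v))
    }
    stop("unknown allele '", name, "' for ", gene)
}

#' Classify a diplotype under the categorical array-style rules
#'
#' Applies the four categorical phenotype rows used by array-based
#' genotyping software: three or more functional gene copies predict UM
#' (duplication alleles count each copy individually); two absent-function
#' alleles predict PM; reduced-function alleles predict IM; otherwise EM
#' (one or two functional alleles, or an increased-function allele paired
#' with a decreased or absent one).  The rows overlap for mixed
#' normal/reduced pairs; these resolve to EM when the Activity Score is at
#' least 1.5 and to IM otherwise, keeping the two schemes consistent.
#' Unknown-class alleles count as functional (their default activity 1.0).
#'
#' @inheritParams activityScore
#' @return list with \code{label} (PM/IM/EM/UM) and \code{rule} (which row
#'   fired).
#' @examples
#' cat2 <- builtinCatalog()
#' classifyAmpliChipRules(c("*1xN", "*1"), "CYP2D6", cat2)$label  # "UM"
#' classifyAmpliChipRules(c("*4", "*5"), "CYP2D6", cat2)$label    # "PM"
#' classifyAmpliChipRules(c("*17", "*41"), "CYP2D6", cat2)$label  # "IM"
#' @export
classifyAmpliChipRules <- function(pair, gene, catalog,
                                   novelActivities = NULL) {
    stopifnot(length(pair) == 2L)
    info <- lapply(pair, .alleleInfo, gene = gene, catalog = catalog,
                   novelActivities = novelActivities)
    cls <- vapply(info, `[[`, character(1), "class")
    cp <- vapply(info, `[[`, integer(1), "copies")
    as_ <- sum(vapply(info, `[[`, numeric(1), "value"))
    functional <- sum(cp[cls %in% c("normal", "increased", "unknown")])
    reduced <- sum(cp[cls == "decreased"])
    nAbsent <- sum(cls == "absent")
    if (functional >= 3L)
        list(label = "UM", rule = "3 or more functional alleles")
    else if (nAbsent == 2L)
        list(label = "PM", rule = "2 absent function alleles")
    else if (reduced > 0L && functional > 0L) {
        if (as_ >= 1.5 - 1e-9)
            list(label = "EM",
                 rule = "mixed functional/reduced pair, AS >= 1.5")
        else
            list(label = "IM",
                 rule = "mixed functional/reduced pair, AS < 1.5")
    } else if (reduced > 0L)
        list(label = "IM", rule = "1 or 2 reduced function alleles")
    else
        list(label = "EM",
             rule = paste("1 or 2 functional alleles / increased paired",
                          "with decreased or absent"))
}

#' Stratified phenotype frequency table for a cohort of calls
#'
#' Tallies predicted phenotypes (PM/IM/EM/UM/unknown/no_call/failure) per
#' stratum as percentages of the stratum cohort size, mirroring the
#' "Predicted Phenotype Frequency" blocks of cohort reports.  Percentages
#' sum to 100 within rounding in every stratum.
#'
#' @param calls list of \code{\linkS4class{DiplotypeCall}} objects.
#' @param strata character vector assigning each call to a stratum (same
#'   length and order as \code{calls}).
#' @param scheme \code{"activity_score"} (uses the AS phenotype slot) or
#'   \code{"amplichip_rules"} (uses the categorical-rule slot).
#' @return matrix of percentages, rows the phenotype labels, columns the
#'   strata, with attribute \code{"n"} giving the cohort size per stratum.
#' @export
cohortPhenotypeTable <- function(calls, strata,
                                 scheme = c("activity_score",
                                            "amplichip_rules")) {
    scheme <- match.arg(scheme)
    stopifnot(length(calls) > 0L, length(calls) == length(strata))
    ph <- vapply(calls, function(cc) {
        if (scheme == "amplichip_rules" && !is.na(cc@phenotypeAmplichip) &&
            !cc@phenotype %in% c("no_call", "failure"))
            cc@phenotypeAmplichip
        else cc@phenotype
    }, character(1))
    lv <- unique(strata)
    empty <- setdiff(lv, strata)
    if (length(empty)) {
        warning("empty stratum omitted: ", paste(empty, collapse = ", "))
        lv <- setdiff(lv, empty)
    }
    tab <- table(factor(ph, levels = .PHENOTYPES),
                 factor(strata, levels = lv))
    n <- colSums(tab)
    pct <- sweep(tab, 2L, n, "/") * 100
    m <- matrix(as.numeric(pct), nrow = nrow(pct),
                dimnames = dimnames(pct))
    attr(m, "n") <- stats::setNames(as.numeric(n), colnames(m))
    m
}
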