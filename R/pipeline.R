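## Pipeline stages tying the modules together: simulate -> call ->
## compare, with TSV/JSON report output.  A thin command-line wrapper
## over these functions ships in inst/scripts/pgxstar.R.

#' Simulate a cohort and write it to disk
#'
#' @param gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @param seed integer random seed.
#' @param outDir output directory.
#' @param config a \code{\linkS4class{SimulationConfig}}; default the
#'   stratified 70/10/10/10 cohort.
#' @param profile optional \code{\linkS4class{PlatformProfile}} applied to
#'   corrupt the truth (e.g. \code{amplichipProfile()}); \code{NULL}
#'   writes the error-free truth observations.
#' @param catalog allele catalog.
#' @return the simulation result list (see \code{\link{simulateTruth}}),
#'   invisibly, with attribute \code{"paths"}.
#' @export
runSimulate <- function(gene = c("CYP2D6", "CYP2C19"), seed, outDir,
                        config = NULL, profile = NULL,
                        catalog = builtinCatalog()) {
    gene <- match.arg(gene)
    if (is.null(config)) config <- defaultCohortConfig(gene, catalog = catalog)
    sim <- simulateTruth(config, seed, catalog)
    if (!is.null(profile))
        sim <- applyPlatformModel(sim, profile, seed + 1L, catalog)
    paths <- writeCohort(sim, outDir, config)
    attr(sim, "paths") <- paths
    invisible(sim)
}

.failureCall <- function(id, gene, status) {
    new("DiplotypeCall", sampleId = id, gene = gene,
        primary = c(NA_character_, NA_character_), alternatives = list(),
        activityScore = NA_real_, phenotype = status,
        phenotypeAmplichip = NA_character_, ruleFired = NA_character_,
        novelCandidates = list(), notes = paste("platform", status))
}

#' Call diplotypes and phenotypes for a cohort directory
#'
#' Reads a cohort written by \code{\link{writeCohort}} (or
#' \code{\link{runSimulate}}), calls every sample with
#' \code{\link{callSample}}, and optionally writes a calls TSV plus a
#' stratified phenotype report.  Samples the platform failed on are
#' carried through as \code{failure} / \code{no_call} rows.
#'
#' @param dir cohort directory.
#' @param catalog allele catalog.
#' @param scheme \code{"activity_score"}, \code{"amplichip_rules"} or
#'   \code{"both"}.
#' @param outDir optional directory for \code{calls.tsv} and
#'   \code{phenotype_frequency.tsv} (plus JSON mirrors).
#' @return list with \code{calls} (list of
#'   \code{\linkS4class{DiplotypeCall}}), \code{table} (calls as a
#'   data.frame), \code{strata}, and \code{phenotypeTable}.
#' @export
runCall <- function(dir, catalog = builtinCatalog(),
                    scheme = c("activity_score", "amplichip_rules", "both"),
                    outDir = NULL) {
    scheme <- match.arg(scheme)
    coh <- readCohort(dir)
    base <- if (!is.null(coh$observed)) coh$observed else coh$truth
    calls <- vector("list", nrow(base))
    for (i in seq_len(nrow(base))) {
        id <- base$sample[i]
        if (base$status[i] != "ok") {
            calls[[i]] <- .failureCall(id, coh$gene, base$status[i])
        } else if (!is.null(coh$observations[[id]])) {
            calls[[i]] <- callSample(coh$observations[[id]], catalog, scheme)
        } else {
            calls[[i]] <- .failureCall(id, coh$gene, "no_call")
        }
    }
    strata <- base$stratum
    pt <- cohortPhenotypeTable(calls, strata,
                               scheme = if (scheme == "amplichip_rules")
                                   "amplichip_rules" else "activity_score")
    tab <- data.frame(
        sample = vapply(calls, function(x) x@sampleId, character(1)),
        gene = coh$gene,
        stratum = strata,
        diplotype = vapply(calls, function(x)
            if (anyNA(x@primary)) "" else paste(x@primary, collapse = "/"),
            character(1)),
        alternatives = vapply(calls, function(x)
            paste(vapply(x@alternatives, paste, character(1),
                         collapse = "/"), collapse = ";"), character(1)),
        activity_score = vapply(calls, function(x) x@activityScore,
                                numeric(1)),
        phenotype = vapply(calls, function(x) x@phenotype, character(1)),
        phenotype_amplichip = vapply(calls, function(x)
            x@phenotypeAmplichip, character(1)),
        novel_candidates = vapply(calls, function(x)
            paste(vapply(x@novelCandidates, function(nc)
                paste0(nc@backbone, "+",
                       paste(nc@extraVariants, collapse = ",")),
                character(1)), collapse = ";"), character(1)),
        notes = vapply(calls, function(x)
            paste(x@notes, collapse = "; "), character(1)),
        stringsAsFactors = FALSE)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        hdr <- .provenance_header(coh$seed)
        .write_tsv(tab, file.path(outDir, "calls.tsv"), hdr)
        ptdf <- data.frame(phenotype = rownames(pt), pt,
                           check.names = FALSE)
        .write_tsv(ptdf, file.path(outDir, "phenotype_frequency.tsv"), hdr)
        jsonlite::write_json(
            list(provenance = hdr, calls = tab,
                 phenotype_frequency = as.data.frame(ptdf)),
            file.path(outDir, "calls.json"), auto_unbox = TRUE, digits = NA)
    }
    list(calls = calls, table = tab, strata = strata, phenotypeTable = pt)
}

#' Compare two call sets (platform concordance report)
#'
#' Runs \code{\link{platformConcordance}} and adds a functional-class
#' breakdown of the allele counts on each side.
#'
#' @param callsA,callsB call tables (data.frame with \code{sample},
#'   \code{allele1}, \code{allele2}, optional \code{status}) or lists of
#'   \code{DiplotypeCall}; side A is the reference platform.
#' @param gene gene name.
#' @param catalog allele catalog.
#' @param outDir optional output directory for the TSV + JSON report.
#' @return the \code{\link{platformConcordance}} list extended with
#'   \code{breakdownA} and \code{breakdownB}.
#' @export
runCompare <- function(callsA, callsB, gene, catalog = builtinCatalog(),
                       outDir = NULL) {
    conc <- platformConcordance(callsA, callsB)
    cnt <- function(per, col) stats::setNames(per[[col]], per$allele)
    bd <- function(counts) tryCatch(
        functionalClassBreakdown(counts, catalog, gene),
        error = function(e) NULL)
    conc$breakdownA <- bd(cnt(conc$perAllele, "countA"))
    conc$breakdownB <- bd(cnt(conc$perAllele, "countB"))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        hdr <- .provenance_header(NA)
        .write_tsv(conc$perAllele, file.path(outDir, "concordance.tsv"), hdr)
        mm <- conc$miscallMatrix
        jsonlite::write_json(
            list(provenance = hdr, agreement = conc$agreement,
                 n_compared = conc$nCompared,
                 excluded = as.list(conc$excluded),
                 per_allele = conc$perAllele,
                 miscall_matrix = list(truth = rownames(mm),
                                       called = colnames(mm),
                                       counts = mm)),
            file.path(outDir, "concordance.json"), auto_unbox = TRUE,
            digits = NA, matrix = "rowmajor")
    }
    conc
}
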