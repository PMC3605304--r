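## Cohort file I/O: tab-separated variant / CNV / truth tables, a minimal
## VCF v4.2 emitter with gene-local coordinate offsets, and ingestion of
## printed frequency tables.

.VCF_OFFSET <- 5000L   # gene-local position -> VCF POS (no position 0)

.provenance_header <- function(seed, extra = "") {
    ver <- tryCatch(as.character(utils::packageVersion("PGxStar")),
                    error = function(e) "dev")
    paste0("# PGxStar ", ver, "; seed=", seed,
           if (nzchar(extra)) paste0("; ", extra) else "")
}

.write_tsv <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.obs_to_frames <- function(observations) {
    var_rows <- list(); cnv_rows <- list()
    for (o in observations) {
        cl <- o@calls
        if (nrow(cl))
            var_rows[[length(var_rows) + 1L]] <- data.frame(
                sample = o@sampleId, gene = o@gene, label = cl$label,
                zygosity = cl$zygosity,
                phase_set = ifelse(is.na(cl$phaseSet), "", cl$phaseSet),
                stringsAsFactors = FALSE)
        cnv_rows[[length(cnv_rows) + 1L]] <- data.frame(
            sample = o@sampleId, gene = o@gene,
            deletion_copies = o@deletionCopies,
            duplication_present = o@duplicationPresent,
            duplicated_allele_hint = paste(
                o@duplicatedAlleleHint[!is.na(o@duplicatedAlleleHint)],
                collapse = ","),
            exon9_conversion = o@exon9Conversion, stringsAsFactors = FALSE)
    }
    list(variants = if (length(var_rows)) do.call(rbind, var_rows)
         else data.frame(sample = character(), gene = character(),
                         label = character(), zygosity = character(),
                         phase_set = character()),
         cnv = do.call(rbind, cnv_rows))
}

#' Write a simulated cohort to disk
#'
#' Emits the variant table (TSV and minimal VCF v4.2), the CNV/conversion
#' sidecar, the truth labels, the observed diplotypes when a platform
#' model was applied, and the simulation provenance (seed, package
#' version) as a YAML config.  All files carry a provenance header line
#' and re-load to equal objects via \code{\link{readCohort}}.
#'
#' @param sim result of \code{\link{simulateTruth}} or
#'   \code{\link{applyPlatformModel}}.
#' @param dir output directory (created if needed).
#' @param config optional \code{\linkS4class{SimulationConfig}} recorded
#'   for provenance.
#' @return named character vector of file paths, invisibly.
#' @export
writeCohort <- function(sim, dir, config = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .provenance_header(sim$seed)
    paths <- c(truth = file.path(dir, "truth.tsv"),
               variants = file.path(dir, "variants.tsv"),
               cnv = file.path(dir, "cnv.tsv"),
               vcf = file.path(dir, "variants.vcf"),
               config = file.path(dir, "config.yaml"))
    .write_tsv(sim$truth, paths[["truth"]], hdr)
    fr <- .obs_to_frames(sim$observations)
    .write_tsv(fr$variants, paths[["variants"]], hdr)
    .write_tsv(fr$cnv, paths[["cnv"]], hdr)
    writeVcfCohort(sim$observations, paths[["vcf"]], seed = sim$seed)
    if (!is.null(sim$observed)) {
        paths <- c(paths, observed = file.path(dir, "observed.tsv"))
        .write_tsv(sim$observed, paths[["observed"]], hdr)
    }
    cfg <- list(gene = sim$gene, seed = sim$seed,
                package = .provenance_header(sim$seed))
    if (!is.null(config))
        cfg <- c(cfg, list(strata = as.list(config@strataSizes),
                           frequencies = lapply(config@frequencies,
                                                as.list)))
    yaml::write_yaml(cfg, paths[["config"]])
    invisible(paths)
}

#' Read a cohort directory written by writeCohort
#'
#' @param dir cohort directory.
#' @return a list with \code{truth}, \code{observed} (or \code{NULL}),
#'   \code{observations} (named list of
#'   \code{\linkS4class{ObservedGenotype}}), \code{gene} and \code{seed}.
#' @export
readCohort <- function(dir) {
    rd <- function(f) utils::read.table(
        file.path(dir, f), sep = "\t", header = TRUE, comment.char = "#",
        colClasses = "character", quote = "")
    truth <- rd("truth.tsv")
    cnv <- rd("cnv.tsv")
    vars <- rd("variants.tsv")
    cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
    obs <- list()
    for (i in seq_len(nrow(cnv))) {
        id <- cnv$sample[i]
        v <- vars[vars$sample == id, , drop = FALSE]
        calls <- if (nrow(v))
            data.frame(label = v$label, zygosity = v$zygosity,
                       phaseSet = ifelse(nzchar(v$phase_set), v$phase_set,
                                         NA_character_),
                       stringsAsFactors = FALSE)
        else NULL
        obs[[id]] <- observedGenotype(
            id, cnv$gene[i], calls,
            deletionCopies = as.integer(cnv$deletion_copies[i]),
            duplicationPresent = as.logical(cnv$duplication_present[i]),
            duplicatedAlleleHint = if (nzchar(cnv$duplicated_allele_hint[i]))
                strsplit(cnv$duplicated_allele_hint[i], ",",
                         fixed = TRUE)[[1]] else NA_character_,
            exon9Conversion = as.logical(cnv$exon9_conversion[i]))
    }
    observed <- if (file.exists(file.path(dir, "observed.tsv")))
        rd("observed.tsv") else NULL
    if (!is.null(observed)) {
        observed$allele1[observed$allele1 == "NA"] <- NA_character_
        observed$allele2[observed$allele2 == "NA"] <- NA_character_
    }
    list(truth = truth, observed = observed, observations = obs,
         gene = cfg$gene, seed = as.integer(cfg$seed))
}

#' Write observations as a minimal VCF v4.2
#'
#' One contig per gene; VCF POS is the gene-local position plus a fixed
#' offset of 5000 (recorded in the header) so upstream/promoter positions
#' remain positive.  Variant labels are carried in the ID column.
#' Insertions and deletions use an \code{N} anchor base.  Genotypes are
#' unphased \code{GT} values.
#'
#' @param observations named list of
#'   \code{\linkS4class{ObservedGenotype}}.
#' @param path output path.
#' @param seed provenance seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
writeVcfCohort <- function(observations, path, seed = NA) {
    samples <- names(observations)
    genes <- unique(vapply(observations, function(o) o@gene, character(1)))
    allv <- unique(do.call(rbind, lapply(observations, function(o)
        if (nrow(o@calls)) data.frame(gene = o@gene, label = o@calls$label,
                                      stringsAsFactors = FALSE))))
    lines <- c("##fileformat=VCFv4.2",
               paste0("##source=PGxStar; seed=", seed),
               paste0("##pgxstar_gene_local_offset=", .VCF_OFFSET),
               paste0("##contig=<ID=", genes, ",length=50000>"),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"))
    if (!is.null(allv) && nrow(allv)) {
        p <- parseVariantLabel(allv$label)
        ref <- ifelse(p$kind == "SNV", p$ref,
                      ifelse(p$kind == "insertion", "N",
                             paste0("N", p$ref)))
        alt <- ifelse(p$kind == "SNV", p$alt,
                      ifelse(p$kind == "insertion", paste0("N", p$alt),
                             "N"))
        pos <- p$position + .VCF_OFFSET
        o <- order(allv$gene, pos)
        allv <- allv[o, , drop = FALSE]
        ref <- ref[o]; alt <- alt[o]; pos <- pos[o]
        gts <- vapply(seq_len(nrow(allv)), function(i) {
            paste(vapply(samples, function(s) {
                oo <- observations[[s]]
                if (oo@gene != allv$gene[i]) return("./.")
                j <- match(allv$label[i], oo@calls$label)
                if (is.na(j)) "0/0"
                else if (oo@calls$zygosity[j] == "hom") "1/1" else "0/1"
            }, character(1)), collapse = "\t")
        }, character(1))
        lines <- c(lines,
                   paste(allv$gene, pos, allv$label, ref, alt, ".",
                         "PASS", ".", "GT", gts, sep = "\t"))
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a PGxStar cohort VCF into variant observations
#'
#' Parses the file with \code{VariantAnnotation::readVcf} (so the file
#' must be strictly valid VCF), inverts the gene-local offset, and
#' rebuilds per-sample calls.  CNV and conversion flags live in the TSV
#' sidecar, not the VCF; the returned genotypes carry only variant calls.
#'
#' @param path VCF file path.
#' @return named list of \code{\linkS4class{ObservedGenotype}}.
#' @export
readVcfCohort <- function(path) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    rr <- SummarizedExperiment::rowRanges(vcf)
    gene <- as.character(GenomeInfoDb::seqnames(rr))
    labels <- names(rr)
    samples <- colnames(gt)
    obs <- list()
    for (s in samples) {
        keep <- gt[, s] %in% c("0/1", "1/1", "0|1", "1|0", "1|1")
        if (!any(keep)) {
            g <- unique(gene)[1]
            obs[[s]] <- observedGenotype(s, g, NULL)
            next
        }
        calls <- data.frame(
            label = labels[keep],
            zygosity = ifelse(gt[keep, s] %in% c("1/1", "1|1"),
                              "hom", "het"),
            phaseSet = NA_character_, stringsAsFactors = FALSE)
        obs[[s]] <- observedGenotype(s, unique(gene[keep])[1], calls)
    }
    obs
}

#' Ingest a printed stratified frequency table
#'
#' Reads a TSV with an \code{allele} column, one column per stratum of
#' percent frequencies, and a final row named \code{alleles_identified}
#' holding the per-stratum denominators.
#'
#' @param path TSV path.
#' @param gene gene name for the resulting table.
#' @return a \code{\linkS4class{CohortTable}}.
#' @export
loadCohortTable <- function(path, gene) {
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             comment.char = "#", check.names = FALSE)
    stopifnot(names(raw)[1] == "allele")
    deni <- which(raw$allele == "alleles_identified")
    if (length(deni) != 1L)
        stop("frequency table needs an 'alleles_identified' denominator row")
    den <- as.numeric(raw[deni, -1])
    names(den) <- names(raw)[-1]
    fr <- as.matrix(raw[-deni, -1])
    rownames(fr) <- raw$allele[-deni]
    cohortTable(fr, den, gene)
}
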