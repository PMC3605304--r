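## Allele catalog construction, accessors and I/O.

.allele_row <- function(gene, name, class, cnv = 1L, base = NA_character_,
                        key = character(), backbone = character(),
                        ann = list()) {
    data.frame(gene = gene, name = name, activityClass = class,
               activityValue = unname(.ACTIVITY_CLASSES[class]),
               cnvMultiplier = as.integer(cnv), baseAllele = base,
               keyVariants = I(list(key)), backboneVariants = I(list(backbone)),
               annotations = I(list(ann)), stringsAsFactors = FALSE)
}

#' Built-in CYP2D6 / CYP2C19 star-allele catalog
#'
#' The catalog of star alleles used throughout the package, covering every
#' allele relevant to the South African cohort analyses this package
#' implements: the CYP2D6 alleles detectable by gene re-sequencing
#' (including the novel *4P, *84, *85 and *86 haplotypes, the whole-gene
#' deletion *5, the xN duplication alleles and the exon-9 conversion
#' products *4N and *36) and the CYP2C19 alleles assayed by PCR-RFLP
#' (including the promoter variant allele *27 and the hybrid *2+*27
#' haplotype that carries both the 19154G>A splice defect and the -1401G>A
#' promoter SNP).
#'
#' Activity classes follow the standard nomenclature assignments:
#' increased = 2.0, normal = 1.0, decreased = 0.5, absent = 0.0; alleles of
#' unknown activity default to 1.0 for scoring.  Alleles whose defining
#' SNPs are taken from the public nomenclature tables rather than
#' measurements native to this package carry
#' \code{provenance = "external-nomenclature"} in their annotations; code
#' should not rely on those placeholder positions.
#'
#' @return an \code{\linkS4class{AlleleCatalog}}.
#' @examples
#' cat2 <- builtinCatalog()
#' activityOf(cat2, "CYP2D6", "*17")   # 0.5
#' activityOf(cat2, "CYP2D6", "*2xN")  # 2.0
#' @export
builtinCatalog <- function() {
    ext <- list(provenance = "external-nomenclature")
    d6 <- rbind(
        .allele_row("CYP2D6", "*1", "normal"),
        .allele_row("CYP2D6", "*2", "normal",
                    key = c("2850C>T", "4180G>C"),
                    backbone = "-1584C>G",
                    ann = c(ext, list(consequence = "R296C;S486T"))),
        .allele_row("CYP2D6", "*4", "absent",
                    key = c("100C>T", "1846G>A"),
                    ann = list(consequence = "splice defect",
                               note = "1846G>A causes aberrant splicing")),
        .allele_row("CYP2D6", "*4N", "absent",
                    key = c("100C>T", "1846G>A", "4388C>T"),
                    ann = c(ext, list(conversionOf = "*4",
                                      note = "exon 9 CYP2D7 conversion"))),
        .allele_row("CYP2D6", "*4P", "absent",
                    key = c("100C>T", "1846G>A", "4157T>G"),
                    ann = list(note = paste("novel; 4157T>G linked with the",
                                            "1846G>A splice defect, AS 0"))),
        .allele_row("CYP2D6", "*5", "absent", cnv = 0L,
                    ann = list(note = "whole-gene deletion")),
        .allele_row("CYP2D6", "*10", "decreased",
                    key = "100C>T", backbone = "4180G>C",
                    ann = list(consequence = "P34S")),
        .allele_row("CYP2D6", "*14", "absent", key = "1758G>A"),
        .allele_row("CYP2D6", "*16", "absent", key = "214G>C", ann = ext),
        .allele_row("CYP2D6", "*17", "decreased",
                    key = c("1023C>T", "2850C>T", "4180G>C"),
                    ann = c(ext, list(consequence = "T107I;R296C"))),
        .allele_row("CYP2D6", "*22", "normal", key = "82C>T", ann = ext),
        .allele_row("CYP2D6", "*25", "unknown", key = "3198C>G", ann = ext),
        .allele_row("CYP2D6", "*29", "decreased",
                    key = c("1659G>A", "2850C>T", "3183G>A", "4180G>C"),
                    ann = ext),
        .allele_row("CYP2D6", "*30", "unknown",
                    key = "1863insTTTCGCCCC", ann = ext),
        .allele_row("CYP2D6", "*33", "normal", key = "2483G>T", ann = ext),
        .allele_row("CYP2D6", "*35", "normal",
                    key = c("31G>A", "2850C>T", "4180G>C"),
                    backbone = "-1584C>G", ann = ext),
        .allele_row("CYP2D6", "*36", "decreased",
                    key = c("100C>T", "4388C>T"),
                    ann = c(ext, list(conversionOf = "*10",
                                      note = "exon 9 CYP2D7 conversion"))),
        .allele_row("CYP2D6", "*40", "absent",
                    key = c("1023C>T", "1863insTTTCGCCCC", "2850C>T",
                            "4180G>C"), ann = ext),
        .allele_row("CYP2D6", "*41", "decreased",
                    key = c("2850C>T", "2988G>A", "4180G>C"),
                    ann = list(note = paste("key SNP 2988G>A; array",
                                            "platforms designate *41 by",
                                            "-1584C>G linkage instead"))),
        .allele_row("CYP2D6", "*43", "normal", key = "77G>A", ann = ext),
        .allele_row("CYP2D6", "*45B", "normal",
                    key = c("1716G>A", "2850C>T", "4180G>C"), ann = ext),
        .allele_row("CYP2D6", "*46", "normal",
                    key = c("77G>A", "1716G>A", "2850C>T", "4180G>C"),
                    ann = ext),
        .allele_row("CYP2D6", "*56B", "absent", key = "3201C>T", ann = ext),
        .allele_row("CYP2D6", "*59", "decreased",
                    key = c("2850C>T", "2939G>A", "4180G>C"), ann = ext),
        .allele_row("CYP2D6", "*64", "unknown", key = "3853G>A", ann = ext),
        .allele_row("CYP2D6", "*65", "unknown", key = "2097A>G", ann = ext),
        .allele_row("CYP2D6", "*73", "unknown", key = "3790C>T", ann = ext),
        .allele_row("CYP2D6", "*74", "unknown", key = "1012G>A", ann = ext),
        .allele_row("CYP2D6", "*84", "unknown",
                    key = c("2574C>A", "2850C>T", "4180G>C"),
                    backbone = "-1584C>G",
                    ann = list(consequence = "P267H", SIFT = 0.03,
                               PolyPhen = 0.871,
                               note = "novel; *2 backbone; AS 1.0")),
        .allele_row("CYP2D6", "*85", "unknown",
                    key = c("2850C>T", "4157T>G", "4180G>C"),
                    backbone = "-1584C>G",
                    ann = list(consequence = "H478Q", SIFT = 0.58,
                               PolyPhen = 0.419,
                               note = "novel; *2 backbone; AS 1.0")),
        .allele_row("CYP2D6", "*86", "unknown",
                    key = c("2606G>A", "2610T>A"),
                    ann = list(consequence = "E278K;M279K", SIFT = 0.01,
                               PolyPhen = 1.905,
                               note = "novel; AS 1.0")),
        .allele_row("CYP2D6", "*1xN", "increased", cnv = 2L, base = "*1"),
        .allele_row("CYP2D6", "*2xN", "increased", cnv = 2L, base = "*2"),
        .allele_row("CYP2D6", "*4xN", "absent", cnv = 2L, base = "*4"))
    c19 <- rbind(
        .allele_row("CYP2C19", "*1", "normal"),
        .allele_row("CYP2C19", "*2", "absent", key = "19154G>A",
                    ann = list(note = "splice defect")),
        .allele_row("CYP2C19", "*3", "absent", key = "17948G>A", ann = ext),
        .allele_row("CYP2C19", "*9", "decreased", key = "12784G>A",
                    ann = ext),
        .allele_row("CYP2C19", "*15", "unknown", key = "55A>C", ann = ext),
        .allele_row("CYP2C19", "*17", "increased", key = "-806C>T",
                    ann = ext),
        .allele_row("CYP2C19", "*27", "decreased", key = "-1401G>A",
                    ann = list(note = paste("promoter SNP; also reported",
                                            "as -1041G>A in places; -1401",
                                            "retained"))),
        .allele_row("CYP2C19", "*28", "normal", key = "19006G>A",
                    ann = ext),
        .allele_row("CYP2C19", "*2+*27", "absent",
                    key = c("-1401G>A", "19154G>A"),
                    ann = list(reportedAs = "*2",
                               note = paste("hybrid haplotype carrying both",
                                            "defining SNPs; the 19154G>A",
                                            "splice defect is",
                                            "allele-defining, so activity",
                                            "equals *2"))))
    new("AlleleCatalog", alleles = rbind(d6, c19))
}

#' @describeIn builtinCatalog genes present in a catalog.
#' @param catalog an \code{AlleleCatalog}.
#' @export
catalogGenes <- function(catalog) unique(catalog@alleles$gene)

#' Allele names of one gene in a catalog
#' @param catalog an \code{AlleleCatalog}.
#' @param gene gene name.
#' @export
alleleNames <- function(catalog, gene) {
    catalog@alleles$name[catalog@alleles$gene == gene]
}

#' Retrieve one allele definition
#'
#' @param catalog an \code{AlleleCatalog}.
#' @param gene gene name.
#' @param name star-allele name.
#' @return a list with elements \code{gene}, \code{name},
#'   \code{activityClass}, \code{activityValue}, \code{cnvMultiplier},
#'   \code{baseAllele}, \code{keyVariants}, \code{backboneVariants},
#'   \code{annotations}.
#' @export
getAllele <- function(catalog, gene, name) {
    al <- catalog@alleles
    i <- which(al$gene == gene & al$name == name)
    if (length(i) != 1L)
        stop("allele '", name, "' not found in catalog for ", gene)
    list(gene = al$gene[i], name = al$name[i],
         activityClass = al$activityClass[i],
         activityValue = al$activityValue[i],
         cnvMultiplier = al$cnvMultiplier[i],
         baseAllele = al$baseAllele[i],
         keyVariants = al$keyVariants[[i]],
         backboneVariants = al$backboneVariants[[i]],
         annotations = al$annotations[[i]])
}

#' Numeric activity value of an allele
#'
#' Looks up the numeric activity of a star allele.  Duplication alleles
#' (\code{"xN"} suffix) return the base allele's activity times the copy
#' count (two copies), whether or not the xN form is itself a catalog
#' entry, so e.g. \code{"*17xN"} resolves to 1.0.
#'
#' @param catalog an \code{AlleleCatalog}.
#' @param gene gene name.
#' @param name star-allele name (possibly an xN duplication form).
#' @return numeric activity value.
#' @examples
#' activityOf(builtinCatalog(), "CYP2D6", "*5")    # 0.0
#' activityOf(builtinCatalog(), "CYP2C19", "*17")  # 2.0
#' @export
activityOf <- function(catalog, gene, name) {
    al <- catalog@alleles
    i <- which(al$gene == gene & al$name == name)
    if (length(i) == 1L) return(al$activityValue[i])
    if (grepl("xN$", name)) {
        base <- sub("xN$", "", name)
        j <- which(al$gene == gene & al$name == base)
        if (length(j) == 1L) return(2 * al$activityValue[j])
    }
    stop("unknown allele '", name, "' for ", gene)
}

## numeric index used for deterministic diplotype ordering: the sum of the
## star numbers of all "+"-joined components ("*2+*27" -> 29); xN keeps the
## base number.  Novel candidates sort last.
.starNumber <- function(name) {
    vapply(name, function(nm) {
        if (grepl("^novel\\(", nm)) return(Inf)
        parts <- strsplit(sub("xN$", "", nm), "+", fixed = TRUE)[[1]]
        num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", parts)))
        if (anyNA(num)) Inf else sum(num)
    }, numeric(1))
}

#' Save a catalog to a tab-separated file
#'
#' One allele per row with columns \code{gene}, \code{name},
#' \code{key_variants} and \code{backbone_variants} (comma-joined labels),
#' \code{activity_class}, \code{activity_value}, \code{cnv_multiplier},
#' \code{base_allele} and \code{annotations} (JSON-in-cell).  Header row
#' mandatory.  \code{loadCatalog} inverts \code{saveCatalog} exactly.
#'
#' @param catalog an \code{AlleleCatalog}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveCatalog <- function(catalog, path) {
    al <- catalog@alleles
    out <- data.frame(
        gene = al$gene, name = al$name,
        key_variants = vapply(al$keyVariants, paste, character(1),
                              collapse = ","),
        backbone_variants = vapply(al$backboneVariants, paste, character(1),
                                   collapse = ","),
        activity_class = al$activityClass,
        activity_value = al$activityValue,
        cnv_multiplier = al$cnvMultiplier,
        base_allele = ifelse(is.na(al$baseAllele), "", al$baseAllele),
        annotations = vapply(al$annotations, function(a)
            as.character(jsonlite::toJSON(a, auto_unbox = TRUE)),
            character(1)),
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Load a catalog from a tab-separated file
#'
#' @param path file written by \code{\link{saveCatalog}} (or following the
#'   same schema).
#' @return an \code{\linkS4class{AlleleCatalog}}.
#' @export
loadCatalog <- function(path) {
    if (!file.exists(path)) stop("catalog file not found: ", path)
    raw <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = "character", quote = "",
                             comment.char = "")
    if (nrow(raw) == 0L) stop("no alleles in catalog file: ", path)
    need <- c("gene", "name", "key_variants", "backbone_variants",
              "activity_class", "activity_value", "cnv_multiplier",
              "base_allele", "annotations")
    miss <- setdiff(need, names(raw))
    if (length(miss))
        stop("malformed catalog file, missing column(s): ",
             paste(miss, collapse = ", "))
    split_labels <- function(x) {
        if (!nzchar(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
    }
    rows <- lapply(seq_len(nrow(raw)), function(i) {
        r <- raw[i, ]
        av <- suppressWarnings(as.numeric(r$activity_value))
        cm <- suppressWarnings(as.integer(r$cnv_multiplier))
        if (is.na(av) || is.na(cm))
            stop("malformed catalog row at line ", i + 1L, " (",
                 r$gene, " ", r$name, ")")
        ann <- if (nzchar(r$annotations))
            jsonlite::fromJSON(r$annotations, simplifyVector = TRUE)
        else list()
        df <- .allele_row(r$gene, r$name, r$activity_class, cnv = cm,
                          base = if (nzchar(r$base_allele)) r$base_allele
                                 else NA_character_,
                          key = split_labels(r$key_variants),
                          backbone = split_labels(r$backbone_variants),
                          ann = as.list(ann))
        if (df$activityValue != av)
            stop("activity value mismatch at line ", i + 1L, " (",
                 r$gene, " ", r$name, "): class '", r$activity_class,
                 "' implies ", df$activityValue, " but file says ", av)
        df
    })
    al <- do.call(rbind, rows)
    dup <- duplicated(paste(al$gene, al$name))
    if (any(dup))
        stop("duplicate allele name(s) in catalog file: ",
             paste(unique(paste(al$gene[dup], al$name[dup])), collapse = ", "))
    new("AlleleCatalog", alleles = al)
}
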