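## Star-allele and diplotype assignment from per-sample variant
## observations, integrating CNV and exon-9 gene-conversion evidence.

#' Construct an ObservedGenotype
#'
#' @param sampleId sample identifier.
#' @param gene \code{"CYP2D6"} or \code{"CYP2C19"}.
#' @param calls a \code{data.frame} with columns \code{label},
#'   \code{zygosity} (\code{"het"}/\code{"hom"}) and optionally
#'   \code{phaseSet}; or \code{NULL} for no variant calls.
#' @param deletionCopies number of *5 deletion alleles (0--2) reported by
#'   the duplex long-range PCR assay.
#' @param duplicationPresent logical duplication assay result.
#' @param duplicatedAlleleHint allele name of the duplicated copy (from
#'   sequencing the duplication-specific product), or \code{NA}.
#' @param exon9Conversion logical exon-9 gene-conversion assay result.
#' @return an \code{\linkS4class{ObservedGenotype}}.
#' @export
observedGenotype <- function(sampleId, gene, calls = NULL,
                             deletionCopies = 0L,
                             duplicationPresent = FALSE,
                             duplicatedAlleleHint = NA_character_,
                             exon9Conversion = FALSE) {
    if (is.null(calls))
        calls <- data.frame(label = character(), zygosity = character(),
                            phaseSet = character(), stringsAsFactors = FALSE)
    if (is.null(calls$phaseSet)) calls$phaseSet <- NA_character_
    calls$phaseSet <- as.character(calls$phaseSet)
    new("ObservedGenotype", sampleId = as.character(sampleId), gene = gene,
        calls = calls[, c("label", "zygosity", "phaseSet")],
        deletionCopies = as.integer(deletionCopies),
        duplicationPresent = isTRUE(duplicationPresent),
        duplicatedAlleleHint = as.character(duplicatedAlleleHint),
        exon9Conversion = isTRUE(exon9Conversion))
}

## label of a resolved haplotype: the allele name, or a synthetic novel tag
.hapName <- function(res) {
    if (is.null(res$novel)) res$name else
        paste0("novel(", res$novel@backbone, "+",
               paste(sort(res$novel@extraVariants), collapse = ","), ")")
}

## null-defining variants: key variants of absent-class alleles that are
## not carried (as key or backbone) by any non-absent allele -- i.e. the
## lesions that themselves abolish function (1846G>A splice defect, etc.),
## not backbone SNPs an absent haplotype happens to share
.nullDefiningVariants <- function(catalog, gene) {
    al <- catalog@alleles[catalog@alleles$gene == gene &
                              catalog@alleles$cnvMultiplier == 1L, ]
    absent <- al$activityClass == "absent"
    inAbsent <- unique(unlist(al$keyVariants[absent]))
    inOther <- unique(unlist(c(al$keyVariants[!absent],
                               al$backboneVariants[!absent])))
    setdiff(inAbsent, inOther)
}

#' Match a phased haplotype variant set to a star allele
#'
#' Returns the catalog allele whose key variants are all present in the
#' variant set and whose key set is maximal (the largest key set wins, so
#' e.g. a haplotype carrying the *2 core plus the *41 key SNP 2988G>A is
#' assigned *41, not *2).  Variants not explained by the winner's key or
#' backbone sets yield a \code{\linkS4class{NovelAlleleCandidate}}.  An
#' empty variant set matches the reference allele *1.  Only
#' sequence-defined alleles (copy-number multiplier 1) take part in
#' matching; the deletion and duplication alleles are assigned from CNV
#' assay evidence by \code{\link{integrateCnv}}.
#'
#' @param variants character vector of variant labels on one haplotype.
#' @param gene gene name.
#' @param catalog an \code{AlleleCatalog}.
#' @param onAmbiguity what to do when two distinct maximal matches of
#'   equal key-set size exist: \code{"error"} (default) stops listing both.
#' @return the allele name (character) when the set is fully explained,
#'   otherwise a \code{NovelAlleleCandidate}.
#' @examples
#' cat2 <- builtinCatalog()
#' matchHaplotype(character(), "CYP2D6", cat2)          # "*1"
#' matchHaplotype("19154G>A", "CYP2C19", cat2)          # "*2"
#' @export
matchHaplotype <- function(variants, gene, catalog,
                           onAmbiguity = c("error", "first")) {
    onAmbiguity <- match.arg(onAmbiguity)
    res <- .resolveHaplotype(variants, gene, catalog, onAmbiguity)
    if (is.null(res$novel)) res$name else res$novel
}

.resolveHaplotype <- function(variants, gene, catalog, onAmbiguity = "error") {
    variants <- unique(variants)
    al <- catalog@alleles
    sub <- al[al$gene == gene & al$cnvMultiplier == 1L, ]
    if (nrow(sub) == 0L) stop("no sequence-defined alleles for ", gene)
    fits <- vapply(sub$keyVariants, function(k) all(k %in% variants),
                   logical(1))
    cand <- sub[fits, ]
    sizes <- lengths(cand$keyVariants)
    winners <- cand$name[sizes == max(sizes)]
    if (length(winners) > 1L) {
        if (onAmbiguity == "error")
            stop("ambiguous haplotype match for ", gene, ": {",
                 paste(sort(variants), collapse = ", "),
                 "} equally matches ", paste(sort(winners), collapse = " and "))
        winners <- sort(winners)[1L]
    }
    win <- cand[cand$name == winners, ]
    explained <- union(win$keyVariants[[1]], win$backboneVariants[[1]])
    extra <- setdiff(variants, explained)
    if (length(extra) == 0L)
        return(list(name = winners, novel = NULL, activity = win$activityValue))
    nullDef <- .nullDefiningVariants(catalog, gene)
    lethal <- intersect(variants, nullDef)
    act <- if (length(lethal)) 0.0 else 1.0
    rationale <- if (length(lethal))
        paste0("carries null-defining variant(s) ",
               paste(lethal, collapse = ", "), "; assigned activity 0.0")
    else "no null-defining variant; novel allele assigned default activity 1.0"
    cnd <- new("NovelAlleleCandidate", backbone = winners,
               extraVariants = extra, assignedActivity = act,
               rationale = rationale)
    list(name = .hapName(list(name = NULL, novel = cnd)), novel = cnd,
         activity = act)
}

#' Detect a novel allele in a haplotype variant set
#'
#' Convenience wrapper: returns the
#' \code{\linkS4class{NovelAlleleCandidate}} when the set is not fully
#' explained by its best catalog match, or \code{NULL} when it is.
#'
#' @inheritParams matchHaplotype
#' @return a \code{NovelAlleleCandidate} or \code{NULL}.
#' @export
detectNovel <- function(variants, gene, catalog) {
    res <- .resolveHaplotype(variants, gene, catalog, onAmbiguity = "first")
    res$novel
}

## normalise a pair of resolutions: lower star number (then name) first
.orderPair <- function(pair) {
    nms <- vapply(pair, .hapName, character(1))
    o <- order(.starNumber(nms), nms)
    pair[o]
}

.pairKey <- function(pair) {
    paste(vapply(pair, .hapName, character(1)), collapse = "/")
}

.pairNovelCount <- function(pair) {
    sum(vapply(pair, function(r) !is.null(r$novel), logical(1)))
}

#' Enumerate diplotypes consistent with unphased variant calls
#'
#' Homozygous calls contribute their variant to both haplotypes; each
#' heterozygous call (or phase-set group of calls) goes to exactly one.
#' All assignments of het groups to the two haplotypes are enumerated,
#' each side is matched with \code{\link{matchHaplotype}}, and the
#' resulting distinct pairs are returned sorted by (fewest novel
#' candidates, lowest combined allele number).  Partitions whose haplotype
#' match is ambiguous are skipped.  The list is never empty: if no
#' partition resolves cleanly the all-on-one-haplotype partition is forced
#' through with novel candidates.
#'
#' @param obs an \code{\linkS4class{ObservedGenotype}}.
#' @param catalog an \code{AlleleCatalog}.
#' @return a list of pairs; each pair is a list of two haplotype
#'   resolutions (elements \code{name}, \code{novel}, \code{activity}).
#'   The first pair is the primary explanation.
#' @examples
#' cat2 <- builtinCatalog()
#' obs <- observedGenotype("s1", "CYP2C19",
#'     data.frame(label = c("19154G>A", "-1401G>A"),
#'                zygosity = "het"))
#' pairs <- enumerateDiplotypes(obs, cat2)
#' sapply(pairs, function(p) paste(sapply(p, `[[`, "name"), collapse = "/"))
#' # "*2/*27" then "*1/*2+*27"
#' @export
enumerateDiplotypes <- function(obs, catalog) {
    gene <- obs@gene
    cl <- obs@calls
    hom <- cl$label[cl$zygosity == "hom"]
    het <- cl[cl$zygosity == "het", , drop = FALSE]
    groups <- if (nrow(het)) {
        gid <- ifelse(is.na(het$phaseSet),
                      paste0(".single.", seq_len(nrow(het))), het$phaseSet)
        unname(split(het$label, gid))
    } else list()
    ng <- length(groups)
    if (ng > 16L)
        stop("too many independent heterozygous phase groups (", ng, ")")
    pairs <- list(); seen <- character()
    masks <- if (ng == 0L) list(logical(0)) else {
        ## fix the first group to side 1 to halve the symmetric space
        lapply(seq_len(2^(max(ng - 1L, 0L))) - 1L, function(m) {
            c(TRUE, as.logical(bitwAnd(rep(m, max(ng - 1L, 0L)),
                                       2^(seq_len(max(ng - 1L, 0L)) - 1L))))
        })
    }
    for (mask in masks) {
        v1 <- unique(c(hom, unlist(groups[mask])))
        v2 <- unique(c(hom, unlist(groups[!mask])))
        pr <- tryCatch(list(.resolveHaplotype(v1, gene, catalog),
                            .resolveHaplotype(v2, gene, catalog)),
                       error = function(e) NULL)
        if (is.null(pr)) next
        pr <- .orderPair(pr)
        key <- .pairKey(pr)
        if (!key %in% seen) { seen <- c(seen, key); pairs <- c(pairs, list(pr)) }
    }
    if (length(pairs) == 0L) {
        v <- unique(cl$label)
        pr <- list(.resolveHaplotype(v, gene, catalog, onAmbiguity = "first"),
                   .resolveHaplotype(character(), gene, catalog))
        pairs <- list(.orderPair(pr))
    }
    nov <- vapply(pairs, .pairNovelCount, numeric(1))
    comb <- vapply(pairs, function(p)
        sum(.starNumber(vapply(p, .hapName, character(1)))), numeric(1))
    keys <- vapply(pairs, .pairKey, character(1))
    comb[!is.finite(comb)] <- .Machine$double.xmax
    pairs[order(nov, comb, keys)]
}

#' Integrate copy-number assay evidence into diplotype explanations
#'
#' One detected deletion allele replaces the second haplotype with *5;
#' the remaining variant calls must then be explicable as a single
#' haplotype (homozygous calls collapse to the one remaining copy).  Two
#' detected deletions force the (*5, *5) diplotype.  A positive
#' duplication assay attaches \code{"xN"} to the allele named by the
#' duplication-specific sequencing hint.
#'
#' @param pairs list of diplotype pairs from
#'   \code{\link{enumerateDiplotypes}}.
#' @param obs the \code{ObservedGenotype} providing the CNV evidence.
#' @param catalog an \code{AlleleCatalog}.
#' @return list with elements \code{pairs} (updated list) and \code{notes}
#'   (character vector).
#' @export
integrateCnv <- function(pairs, obs, catalog) {
    gene <- obs@gene
    notes <- character()
    if (obs@deletionCopies > 0L)
        del5 <- list(name = "*5", novel = NULL,
                     activity = activityOf(catalog, gene, "*5"))
    if (obs@deletionCopies == 2L) {
        pairs <- list(list(del5, del5))
    } else if (obs@deletionCopies == 1L) {
        cl <- obs@calls
        ps <- unique(cl$phaseSet[cl$zygosity == "het" & !is.na(cl$phaseSet)])
        if (length(ps) > 1L)
            stop("deletion assay reports one *5 allele but the variant ",
                 "calls carry ", length(ps), " distinct phase sets, ",
                 "requiring two non-reference haplotypes")
        hap <- .resolveHaplotype(unique(cl$label), gene, catalog)
        pairs <- list(.orderPair(list(hap, del5)))
    }
    if (obs@duplicationPresent) {
        hints <- obs@duplicatedAlleleHint
        hints <- unique(hints[!is.na(hints)])
        if (length(hints) == 0L) {
            notes <- c(notes, paste("duplication present but the duplicated",
                                    "allele was not characterised; xN left",
                                    "unassigned"))
        } else {
            xnify <- function(r) {
                xn <- paste0(r$name, "xN")
                list(name = xn, novel = NULL,
                     activity = activityOf(catalog, gene, xn))
            }
            out <- list(); matched <- FALSE
            for (p in pairs) {
                nms <- vapply(p, function(r)
                    if (is.null(r$name)) "" else r$name, character(1))
                prim <- p; both <- p; extraBoth <- FALSE
                for (h in hints) {
                    idx <- which(nms == h)
                    if (!length(idx)) next
                    matched <- TRUE
                    prim[[idx[1]]] <- xnify(prim[[idx[1]]])
                    for (i in idx) both[[i]] <- xnify(both[[i]])
                    ## a partner identical to the duplicated allele is
                    ## equally consistent with carrying its own extra copy
                    if (length(idx) > 1L) extraBoth <- TRUE
                }
                out <- c(out, list(.orderPair(prim)))
                if (extraBoth) out <- c(out, list(.orderPair(both)))
            }
            seen <- character(); pairs <- list()
            for (p in out) {
                k <- .pairKey(p)
                if (!k %in% seen) { seen <- c(seen, k)
                                    pairs <- c(pairs, list(p)) }
            }
            if (!matched)
                notes <- c(notes, paste0("duplication hint ",
                                         paste(hints, collapse = ","),
                                         " did not match any assigned ",
                                         "haplotype"))
        }
    }
    list(pairs = pairs, notes = notes)
}

#' Relabel alleles according to exon-9 gene-conversion evidence
#'
#' A positive CYP2D7 exon-9 conversion assay marks *4 haplotypes as the
#' non-functional *4N and *10 haplotypes as the reduced-function *36.  A
#' conversion flag on a sample with neither allele appends a note and
#' leaves the pairs untouched.
#'
#' @inheritParams integrateCnv
#' @return list with elements \code{pairs} and \code{notes}.
#' @export
applyExon9Conversion <- function(pairs, obs, catalog) {
    notes <- character()
    if (!obs@exon9Conversion || obs@gene != "CYP2D6")
        return(list(pairs = pairs, notes = notes))
    map <- c("*4" = "*4N", "*10" = "*36")
    hit <- FALSE
    pairs <- lapply(pairs, function(p) {
        p <- lapply(p, function(r) {
            if (!is.null(r$name) && r$name %in% names(map)) {
                hit <<- TRUE
                nm <- unname(map[r$name])
                list(name = nm, novel = NULL,
                     activity = activityOf(catalog, obs@gene, nm))
            } else r
        })
        .orderPair(p)
    })
    if (!hit)
        notes <- c(notes, paste("exon-9 conversion flagged but no *4 or *10",
                                "haplotype present; no relabel applied"))
    list(pairs = pairs, notes = notes)
}

#' Call a sample: diplotype, Activity Score and phenotype
#'
#' Orchestrates diplotype enumeration, CNV integration, exon-9 conversion
#' relabelling and Activity-Score phenotype prediction for one sample at
#' one gene.  Deterministic for a fixed input.  Inconsistencies (e.g. CNV
#' evidence contradicting the variant calls) are reported as a
#' \code{no_call} with a diagnostic note rather than an error.
#'
#' @param obs an \code{\linkS4class{ObservedGenotype}}.
#' @param catalog an \code{AlleleCatalog}.
#' @param scheme phenotype scheme(s) to apply: \code{"activity_score"}
#'   (default), \code{"amplichip_rules"} or \code{"both"}.
#' @return a \code{\linkS4class{DiplotypeCall}}.
#' @examples
#' cat2 <- builtinCatalog()
#' callSample(observedGenotype("s1", "CYP2D6"), cat2)  # *1/*1, AS 2, EM
#' @export
callSample <- function(obs, catalog,
                       scheme = c("activity_score", "amplichip_rules",
                                  "both")) {
    scheme <- match.arg(scheme)
    out <- tryCatch({
        pairs <- enumerateDiplotypes(obs, catalog)
        cnv <- integrateCnv(pairs, obs, catalog)
        e9 <- applyExon9Conversion(cnv$pairs, obs, catalog)
        notes <- c(cnv$notes, e9$notes)
        pairs <- e9$pairs
        primary <- pairs[[1]]
        score <- sum(vapply(primary, `[[`, numeric(1), "activity"))
        novels <- Filter(Negate(is.null), lapply(unlist(pairs,
            recursive = FALSE), `[[`, "novel"))
        if (any(vapply(primary, function(r) {
            !is.null(r$name) && r$name %in% catalog@alleles$name &&
                getAllele(catalog, obs@gene, r$name)$activityClass ==
                    "unknown"
        }, logical(1))))
            notes <- c(notes, "contains-unknown")
        ph <- classifyActivityScore(score)
        amp <- NA_character_; rule <- NA_character_
        if (scheme %in% c("amplichip_rules", "both")) {
            ar <- classifyAmpliChipRules(
                vapply(primary, .hapName, character(1)), obs@gene, catalog,
                novelActivities = .novelActivityMap(primary))
            amp <- ar$label; rule <- ar$rule
            if (scheme == "amplichip_rules") ph <- amp
        }
        new("DiplotypeCall", sampleId = obs@sampleId, gene = obs@gene,
            primary = vapply(primary, .hapName, character(1)),
            alternatives = lapply(pairs[-1], function(p)
                vapply(p, .hapName, character(1))),
            activityScore = score, phenotype = ph,
            phenotypeAmplichip = amp, ruleFired = rule,
            novelCandidates = novels, notes = notes)
    }, error = function(e) {
        new("DiplotypeCall", sampleId = obs@sampleId, gene = obs@gene,
            primary = c(NA_character_, NA_character_), alternatives = list(),
            activityScore = NA_real_, phenotype = "no_call",
            phenotypeAmplichip = NA_character_, ruleFired = NA_character_,
            novelCandidates = list(),
            notes = paste("no_call:", conditionMessage(e)))
    })
    out
}

.novelActivityMap <- function(pair) {
    nms <- vapply(pair, .hapName, character(1))
    act <- vapply(pair, `[[`, numeric(1), "activity")
    stats::setNames(act, nms)
}
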