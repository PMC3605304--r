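#' Parse a variant label into its components
#'
#' Variant labels follow the gene-local nomenclature convention used for
#' pharmacogene haplotype definitions: a 1-based position within the gene
#' reference frame (negative positions are upstream of the ATG; position 0
#' does not exist), followed by the change.  Three kinds are supported:
#' substitutions (\code{"2988G>A"}, \code{"-1584C>G"}), insertions
#' (\code{"1863insTTTCGCCCC"}) and deletions (\code{"2615delAAG"}).
#'
#' @param label character vector of variant labels.
#' @return A \code{data.frame} with one row per label and columns
#'   \code{label}, \code{position} (integer), \code{ref}, \code{alt} and
#'   \code{kind} (one of \code{"SNV"}, \code{"insertion"},
#'   \code{"deletion"}).  Insertions have an empty \code{ref}; deletions an
#'   empty \code{alt}.
#' @examples
#' parseVariantLabel(c("2988G>A", "-1584C>G", "1863insTTTCGCCCC"))
#' @export
parseVariantLabel <- function(label) {
    stopifnot(is.character(label))
    out <- lapply(label, .parse_one_label)
    do.call(rbind, out)
}

.parse_one_label <- function(lab) {
    snv <- regmatches(lab, regexec("^(-?[0-9]+)([ACGT]+)>([ACGT]+)$", lab))[[1]]
    if (length(snv) == 4L) {
        pos <- as.integer(snv[2])
        if (pos == 0L)
            stop("invalid variant label '", lab, "': position 0 does not exist")
        if (snv[3] == snv[4])
            stop("invalid variant label '", lab, "': ref and alt are identical")
        return(data.frame(label = lab, position = pos, ref = snv[3],
                          alt = snv[4], kind = "SNV",
                          stringsAsFactors = FALSE))
    }
    ins <- regmatches(lab, regexec("^(-?[0-9]+)ins([ACGT]+)$", lab))[[1]]
    if (length(ins) == 3L) {
        pos <- as.integer(ins[2])
        if (pos == 0L)
            stop("invalid variant label '", lab, "': position 0 does not exist")
        return(data.frame(label = lab, position = pos, ref = "",
                          alt = ins[3], kind = "insertion",
                          stringsAsFactors = FALSE))
    }
    del <- regmatches(lab, regexec("^(-?[0-9]+)del([ACGT]+)$", lab))[[1]]
    if (length(del) == 3L) {
        pos <- as.integer(del[2])
        if (pos == 0L)
            stop("invalid variant label '", lab, "': position 0 does not exist")
        return(data.frame(label = lab, position = pos, ref = del[3],
                          alt = "", kind = "deletion",
                          stringsAsFactors = FALSE))
    }
    stop("cannot parse variant label '", lab, "'")
}

#' Format variant components back into a label
#'
#' The inverse of \code{\link{parseVariantLabel}}; \code{formatVariantLabel}
#' and \code{parseVariantLabel} round-trip.
#'
#' @param position integer gene-local position (never 0).
#' @param ref,alt reference / alternate sequence (empty string for the
#'   missing side of an insertion or deletion).
#' @param kind one of \code{"SNV"}, \code{"insertion"}, \code{"deletion"}.
#' @return character vector of labels.
#' @export
formatVariantLabel <- function(position, ref, alt,
                               kind = c("SNV", "insertion", "deletion")) {
    kind <- match.arg(kind, several.ok = TRUE)
    stopifnot(all(position != 0L))
    n <- max(length(position), length(ref), length(alt), length(kind))
    position <- rep_len(position, n); ref <- rep_len(ref, n)
    alt <- rep_len(alt, n); kind <- rep_len(kind, n)
    vapply(seq_len(n), function(i) {
        switch(kind[i],
               SNV = {
                   if (ref[i] == alt[i])
                       stop("ref and alt must differ for an SNV")
                   paste0(position[i], ref[i], ">", alt[i])
               },
               insertion = paste0(position[i], "ins", alt[i]),
               deletion = paste0(position[i], "del", ref[i]))
    }, character(1))
}
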