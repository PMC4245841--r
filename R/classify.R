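#' Raw records carrying dbSNP-style loctype codes
#'
#' Small indels in dbSNP-style annotation carry an alignment-type code
#' rather than an explicit INS/DEL call: loctype 1 and loctype 3 cover the
#' small indels this package handles (the range types 4 and 6 are
#' rejected). The empirical resolution — checking whether each allele is
#' present as a reference substring — maps loctype 1 to deletions of the
#' reference and loctype 3 to insertions.
#'
#' @param id,chrom,pos,allele as in [IndelSet()].
#' @param loctype integer code, each value in `{1, 3}`.
#' @return a validated `data.frame` with columns `id`, `chrom`, `pos`,
#'   `loctype`, `allele`.
#' @export
rawLoctypeRecords <- function(id, chrom, pos, loctype, allele) {
    loctype <- as.integer(loctype)
    if (length(loctype) && !all(loctype %in% c(1L, 3L)))
        stop("loctype must be 1 or 3 (small indels); got ",
             loctype[!loctype %in% c(1L, 3L)][1L])
    df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                     pos = as.integer(pos), loctype = loctype,
                     allele = toupper(as.character(allele)),
                     stringsAsFactors = FALSE)
    if (anyDuplicated(df$id)) stop("duplicate ids in loctype records")
    if (nrow(df) && !all(grepl(.ALLELE_RE, df$allele)))
        stop("allele contains characters outside A,C,G,T,N")
    if (nrow(df) && !all(df$pos >= 1L)) stop("pos must be >= 1")
    df
}

#' Is an allele present as a reference substring at a position?
#'
#' `TRUE` iff the window `[pos, pos + nchar(allele) - 1]` lies within the
#' chromosome and the reference substring equals the allele exactly (after
#' uppercasing). An out-of-bounds window is `FALSE`, not an error; an
#' unknown chromosome is an error.
#'
#' @param ref a [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param pos 1-based start of the window.
#' @param allele allele string.
#' @return logical scalar.
#' @export
allelePresentAt <- function(ref, chrom, pos, allele) {
    if (!chrom %in% names(ref))
        stop("unknown chromosome: '", chrom, "'")
    stopifnot(pos >= 1L)
    allele <- toupper(allele)
    end <- pos + nchar(allele) - 1L
    if (end > Biostrings::width(ref)[match(chrom, names(ref))]) return(FALSE)
    refSlice(ref, chrom, pos, end) == allele
}

#' Audit loctype codes against the reference
#'
#' For each loctype value present, counts how many records' alleles occur
#' as the reference substring at their annotated position. A loctype whose
#' alleles are overwhelmingly present behaves as a deletion of the
#' reference. Records on chromosomes absent from the reference are
#' collected separately and excluded from the counts.
#'
#' @param records a `data.frame` from [rawLoctypeRecords()].
#' @param ref a [Biostrings::DNAStringSet].
#' @return list with `audit` (data.frame: `loctype`, `total`, `found`,
#'   `missing`, `fraction_missing`) and `failed` (ids whose chromosome was
#'   not in the reference).
#' @export
auditLoctypes <- function(records, ref) {
    known <- records$chrom %in% names(ref)
    failed <- records$id[!known]
    rec <- records[known, , drop = FALSE]
    if (nrow(rec) == 0L)
        return(list(audit = data.frame(loctype = integer(), total = integer(),
                                       found = integer(), missing = integer(),
                                       fraction_missing = numeric()),
                    failed = failed))
    present <- vapply(seq_len(nrow(rec)), function(i)
        allelePresentAt(ref, rec$chrom[i], rec$pos[i], rec$allele[i]),
        logical(1))
    out <- do.call(rbind, lapply(sort(unique(rec$loctype)), function(lt) {
        sel <- rec$loctype == lt
        total <- sum(sel)
        found <- sum(present[sel])
        data.frame(loctype = lt, total = total, found = found,
                   missing = total - found,
                   fraction_missing = if (total == 0L) 0 else
                       (total - found) / total)
    }))
    rownames(out) <- NULL
    list(audit = out, failed = failed)
}

#' Resolve loctype codes to INS/DEL semantics
#'
#' Loctype 1 becomes `DEL`, loctype 3 becomes `INS` (relative to the
#' reference); any other code is an error. All other fields are copied
#' unchanged, so the mapping is a bijection up to the type field.
#'
#' @param records a `data.frame` from [rawLoctypeRecords()].
#' @return an [IndelSet-class].
#' @export
resolveLoctypes <- function(records) {
    if (nrow(records) && !all(records$loctype %in% c(1L, 3L)))
        stop("cannot resolve loctype ",
             records$loctype[!records$loctype %in% c(1L, 3L)][1L],
             "; only small-indel loctypes 1 and 3 are supported")
    type <- ifelse(records$loctype == 1L, "DEL", "INS")
    IndelSet(records$id, records$chrom, records$pos, type, records$allele)
}

#' Validate deletion records against the reference
#'
#' A deletion whose allele is not the reference substring at its position
#' cannot represent a deletion of the reference, and the template-based
#' redundancy check silently assumes it does. Such records are flagged and
#' excluded before redundancy analysis; insertions are never checked (the
#' inserted allele need not occur in the reference). Flagged records are
#' written to a rejects TSV rather than silently dropped.
#'
#' @param x an [IndelSet-class].
#' @param ref a [Biostrings::DNAStringSet].
#' @param rejectsPath optional path; when given, rejected records are
#'   written as a TSV with the canonical columns plus `reason`.
#' @return list with `pass` (an `IndelSet`) and `rejects` (data.frame of
#'   excluded records with a `reason` column).
#' @export
validateDeletions <- function(x, ref, rejectsPath = NULL) {
    df <- indelRecords(x)
    reason <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        if (!df$chrom[i] %in% names(ref)) {
            reason[i] <- "chromosome not in reference"
        } else if (df$type[i] == "DEL" &&
                   !allelePresentAt(ref, df$chrom[i], df$pos[i], df$allele[i])) {
            reason[i] <- "deletion allele not found in reference at pos"
        }
    }
    bad <- nzchar(reason)
    rejects <- cbind(df[bad, , drop = FALSE],
                     data.frame(reason = reason[bad]))
    rownames(rejects) <- NULL
    if (!is.null(rejectsPath))
        write.table(rejects, rejectsPath, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = TRUE)
    list(pass = x[!bad], rejects = rejects)
}
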