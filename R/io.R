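#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet subseq
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom utils write.table head
NULL

.input_error <- function(...) {
    stop(errorCondition(paste0(...),
                        class = c("redundel_input_error", "error")))
}

#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()] with the conventions used
#' throughout the package: headers are truncated at the first whitespace
#' to form chromosome names, sequences are stored uppercase, duplicate
#' names and empty files are hard errors.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
readReference <- function(path) {
    if (!file.exists(path)) .input_error("reference FASTA not found: ", path)
    ref <- tryCatch(readDNAStringSet(path),
                    error = function(e) .input_error(
                        "cannot parse FASTA '", path, "': ", conditionMessage(e)))
    if (length(ref) == 0L) .input_error("FASTA '", path, "' has no records")
    names(ref) <- sub("\\s.*$", "", names(ref))
    if (anyDuplicated(names(ref)))
        .input_error("duplicate chromosome name in '", path, "': ",
                     names(ref)[duplicated(names(ref))][1L])
    if (any(Biostrings::width(ref) == 0L))
        .input_error("empty sequence for chromosome ",
                     names(ref)[Biostrings::width(ref) == 0L][1L])
    ref
}

#' Extract a reference substring (1-based, inclusive)
#'
#' Returns exactly `end - start + 1` characters or raises; lookups never
#' silently truncate.
#'
#' @param ref a [Biostrings::DNAStringSet].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return character scalar of length `end - start + 1`.
#' @export
refSlice <- function(ref, chrom, start, end) {
    if (!chrom %in% names(ref))
        stop("unknown chromosome: '", chrom, "'")
    w <- Biostrings::width(ref)[match(chrom, names(ref))]
    if (start < 1L || end < start || end > w)
        stop(sprintf("substring [%d, %d] out of bounds for %s (length %d)",
                     start, end, chrom, w))
    as.character(subseq(ref[[chrom]], start, end))
}

#' Length of each chromosome
#' @param ref a [Biostrings::DNAStringSet].
#' @return named integer vector of sequence lengths.
#' @export
chromLengths <- function(ref) {
    stats::setNames(Biostrings::width(ref), names(ref))
}

.TSV_HEADER <- c("id", "chrom", "pos", "type", "allele")

#' Read the canonical indel TSV
#'
#' The canonical table is tab-separated with header
#' `id\tchrom\tpos\ttype\tallele`. Types are case-insensitive `INS`/`DEL`,
#' alleles are uppercased, and the result is sorted by
#' `(chrom, pos, id)`. Malformed rows are reported with their line number.
#'
#' @param path file path.
#' @return an [IndelSet-class].
#' @export
readIndelTsv <- function(path) {
    if (!file.exists(path)) .input_error("indel TSV not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) .input_error("indel TSV '", path, "' is empty")
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!identical(hdr, .TSV_HEADER))
        .input_error("indel TSV header must be '",
                     paste(.TSV_HEADER, collapse = "\\t"), "'")
    body <- lines[-1L]
    if (length(body) == 0L) return(IndelSet())
    fields <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 5L))
        .input_error("line ", which(nf != 5L)[1L] + 1L,
                     ": expected 5 tab-separated fields, found ",
                     nf[nf != 5L][1L])
    m <- do.call(rbind, fields)
    badpos <- !grepl("^[0-9]+$", m[, 3L])
    if (any(badpos))
        .input_error("line ", which(badpos)[1L] + 1L,
                     ": pos is not a non-negative integer: '",
                     m[badpos, 3L][1L], "'")
    badall <- !nzchar(m[, 5L])
    if (any(badall))
        .input_error("line ", which(badall)[1L] + 1L, ": empty allele")
    out <- tryCatch(
        IndelSet(id = m[, 1L], chrom = m[, 2L], pos = as.integer(m[, 3L]),
                 type = m[, 4L], allele = m[, 5L]),
        error = function(e) .input_error("invalid indel TSV '", path, "': ",
                                         conditionMessage(e)))
    out
}

#' Write the canonical indel TSV
#'
#' @param x an [IndelSet-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeIndelTsv <- function(x, path) {
    stopifnot(is(x, "IndelSet"))
    df <- indelRecords(x)[, .TSV_HEADER, drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Convert VCF indel records to the internal representation
#'
#' Only simple anchored indels are convertible: exactly one of REF/ALT has
#' length 1 and that base equals the first base of the longer allele. A
#' record `REF=A, ALT=ATT` at VCF position p becomes an insertion of `TT`
#' at position p + 1 (inserted before that base); `REF=ATT, ALT=A` becomes
#' a deletion of `TT` starting at p + 1. Multi-allelic records contribute
#' one candidate per ALT. SNVs, complex substitutions and symbolic alleles
#' are counted as skipped, not errors.
#'
#' @param path a VCF 4.x text file.
#' @param reference optional [Biostrings::DNAStringSet]; when given, each
#'   record's REF is checked against it and a mismatch is an error naming
#'   the record.
#' @return a list with elements `indels` (an [IndelSet-class]) and
#'   `skipped` (number of non-convertible ALTs).
#' @export
readVcfIndels <- function(path, reference = NULL) {
    if (!file.exists(path)) .input_error("VCF not found: ", path)
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) .input_error(
                      "cannot parse VCF '", path, "': ", conditionMessage(e)))
    fix <- vcfR::getFIX(v)
    if (is.null(fix) || nrow(fix) == 0L)
        return(list(indels = IndelSet(), skipped = 0L))
    id <- chrom <- type <- allele <- character(0)
    pos <- integer(0)
    skipped <- 0L
    for (i in seq_len(nrow(fix))) {
        rchrom <- fix[i, "CHROM"]
        rpos <- as.integer(fix[i, "POS"])
        rref <- toupper(fix[i, "REF"])
        rid <- fix[i, "ID"]
        if (is.na(rid) || rid == ".") rid <- sprintf("var%d", i)
        if (!is.null(reference)) {
            obs <- refSlice(reference, rchrom, rpos, rpos + nchar(rref) - 1L)
            if (obs != rref)
                .input_error("VCF record '", rid, "' REF '", rref,
                             "' disagrees with reference '", obs, "' at ",
                             rchrom, ":", rpos)
        }
        alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1L]]
        multi <- length(alts) > 1L
        for (k in seq_along(alts)) {
            alt <- alts[k]
            aid <- if (multi) sprintf("%s_%d", rid, k) else rid
            simple <- grepl(.ALLELE_RE, alt) && grepl(.ALLELE_RE, rref)
            if (simple && nchar(rref) == 1L && nchar(alt) > 1L &&
                substr(alt, 1L, 1L) == rref) {
                id <- c(id, aid); chrom <- c(chrom, rchrom)
                pos <- c(pos, rpos + 1L); type <- c(type, "INS")
                allele <- c(allele, substring(alt, 2L))
            } else if (simple && nchar(alt) == 1L && nchar(rref) > 1L &&
                       substr(rref, 1L, 1L) == alt) {
                id <- c(id, aid); chrom <- c(chrom, rchrom)
                pos <- c(pos, rpos + 1L); type <- c(type, "DEL")
                allele <- c(allele, substring(rref, 2L))
            } else {
                skipped <- skipped + 1L
            }
        }
    }
    if (anyDuplicated(id)) id <- make.unique(id, sep = "_")
    list(indels = IndelSet(id, chrom, pos, type, allele), skipped = skipped)
}

#' Write a redundancy report to disk
#'
#' Produces the two report artifacts: `<prefix>_clusters.tsv` (one row per
#' cluster member) and `<prefix>_summary.txt` (key-value block with totals
#' and rates; rates printed as percentages with two decimals).
#'
#' @param report a [RedundancyReport-class].
#' @param prefix output path prefix.
#' @return named character vector of the two paths written, invisibly.
#' @export
writeReport <- function(report, prefix) {
    stopifnot(is(report, "RedundancyReport"))
    dir <- dirname(prefix)
    if (!dir.exists(dir))
        .input_error("output directory does not exist: ", dir)
    clusterPath <- paste0(prefix, "_clusters.tsv")
    summaryPath <- paste0(prefix, "_summary.txt")
    write.table(clusterTable(report), clusterPath, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = TRUE)
    s <- redundancySummary(report)
    val <- function(scope, col) s[s$scope == scope, col]
    kv <- c(
        total_indels = val("total", "n"),
        ins_indels = val("INS", "n"),
        del_indels = val("DEL", "n"),
        redundant_total = val("total", "redundant"),
        redundant_ins = val("INS", "redundant"),
        redundant_del = val("DEL", "redundant"),
        redundancy_rate_total = sprintf("%.2f", 100 * val("total", "rate")),
        redundancy_rate_ins = sprintf("%.2f", 100 * val("INS", "rate")),
        redundancy_rate_del = sprintf("%.2f", 100 * val("DEL", "rate")),
        max_distance = report@maxDistance
    )
    writeLines(paste(names(kv), kv, sep = "\t"), summaryPath)
    invisible(c(clusters = clusterPath, summary = summaryPath))
}
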