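#' @importFrom methods new validObject is show setValidity slot
NULL

.INDEL_TYPES <- c("INS", "DEL")
.ALLELE_RE <- "^[ACGTN]+$"

#' IndelSet: a validated table of indel annotations
#'
#' An `IndelSet` holds indel records in the five-field canonical form:
#' `id`, `chrom`, `pos`, `type` and `allele`, plus the derived `length`
#' (always `nchar(allele)`). Coordinates are 1-based and inclusive. For a
#' deletion, `pos` is the first deleted base; for an insertion, the allele
#' is inserted immediately *before* the base at `pos`. Records are kept
#' sorted by `(chrom, pos, id)` so that downstream grouping is
#' deterministic.
#'
#' @slot records a `data.frame` with columns `id`, `chrom`, `pos`, `type`,
#'   `allele`, `length`.
#' @seealso [IndelSet()] for construction, [readIndelTsv()] to read the
#'   canonical TSV.
#' @exportClass IndelSet
setClass("IndelSet", representation(records = "data.frame"))

setValidity("IndelSet", function(object) {
    df <- object@records
    need <- c("id", "chrom", "pos", "type", "allele", "length")
    if (!all(need %in% names(df)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (nrow(df) == 0L) return(TRUE)
    if (anyNA(df[need])) return("records contain NA values")
    if (anyDuplicated(df$id)) {
        dup <- df$id[duplicated(df$id)][1L]
        return(paste0("duplicate indel id: '", dup, "'"))
    }
    if (!all(df$type %in% .INDEL_TYPES))
        return("type must be 'INS' or 'DEL'")
    if (!all(df$pos >= 1L)) return("pos must be >= 1")
    bad <- !grepl(.ALLELE_RE, df$allele)
    if (any(bad))
        return(paste0("allele of '", df$id[bad][1L],
                      "' contains characters outside A,C,G,T,N"))
    if (!all(df$length == nchar(df$allele)))
        return("length must equal nchar(allele)")
    TRUE
})

#' Construct an IndelSet
#'
#' Alleles and types are uppercased on ingest, `length` is derived from the
#' allele, and records are sorted by `(chrom, pos, id)`; ties at identical
#' positions are broken lexicographically by id so that grouping and
#' clustering are deterministic.
#'
#' @param id character vector of unique record identifiers.
#' @param chrom chromosome names.
#' @param pos 1-based positions (first deleted base for `DEL`; insertion
#'   point, i.e. the base the allele precedes, for `INS`).
#' @param type `"INS"` or `"DEL"` (case-insensitive).
#' @param allele allele strings over `A,C,G,T,N` (case-insensitive).
#' @return an [IndelSet-class] object.
#' @examples
#' IndelSet("rs1", "chr1", 5L, "DEL", "AC")
#' @export
IndelSet <- function(id = character(), chrom = character(), pos = integer(),
                     type = character(), allele = character()) {
    df <- data.frame(
        id = as.character(id),
        chrom = as.character(chrom),
        pos = as.integer(pos),
        type = toupper(as.character(type)),
        allele = toupper(as.character(allele)),
        stringsAsFactors = FALSE
    )
    df$length <- nchar(df$allele)
    df <- df[order(df$chrom, df$pos, df$id), , drop = FALSE]
    rownames(df) <- NULL
    new("IndelSet", records = df)
}

#' @describeIn IndelSet number of records.
#' @param x an `IndelSet`.
#' @export
setMethod("length", "IndelSet", function(x) nrow(x@records))

#' Records of an IndelSet as a data.frame
#'
#' @param x an [IndelSet-class].
#' @return the underlying `data.frame` (one row per indel).
#' @export
indelRecords <- function(x) {
    stopifnot(is(x, "IndelSet"))
    x@records
}

#' @export
setMethod("as.data.frame", "IndelSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@records)

#' @export
setMethod("[", "IndelSet", function(x, i, j, ..., drop = TRUE) {
    df <- x@records[i, , drop = FALSE]
    rownames(df) <- NULL
    new("IndelSet", records = df)
})

#' @export
setMethod("show", "IndelSet", function(object) {
    df <- object@records
    cat("IndelSet with", nrow(df), "records")
    if (nrow(df) > 0L) {
        cat(" (", sum(df$type == "INS"), " INS, ",
            sum(df$type == "DEL"), " DEL) on ",
            length(unique(df$chrom)), " chromosome(s)", sep = "")
    }
    cat("\n")
    if (nrow(df) > 0L) print(utils::head(df, 5L))
    if (nrow(df) > 5L) cat("...", nrow(df) - 5L, "more\n")
    invisible(NULL)
})

#' CandidateGroups: chained candidate redundant indel groups
#'
#' Result of [candidateGroups()]: a partition of a subset of an
#' [IndelSet-class] into groups of two or more indels that share
#' chromosome, type and length, with consecutive members no more than
#' `maxDistance` base pairs apart.
#'
#' @slot indels the full input `IndelSet` (groups index into its rows).
#' @slot groups list of integer vectors; each vector holds row indices of
#'   one group's members, sorted by position.
#' @slot maxDistance the distance threshold D used to chain.
#' @exportClass CandidateGroups
setClass("CandidateGroups", representation(
    indels = "IndelSet", groups = "list", maxDistance = "integer"))

setValidity("CandidateGroups", function(object) {
    df <- indelRecords(object@indels)
    for (g in object@groups) {
        if (length(g) < 2L) return("every group must have >= 2 members")
        sub <- df[g, , drop = FALSE]
        if (length(unique(sub$chrom)) != 1L ||
            length(unique(sub$type)) != 1L ||
            length(unique(sub$length)) != 1L)
            return("group members must share chrom, type and length")
        if (is.unsorted(sub$pos))
            return("group members must be sorted by position")
        if (length(g) > 1L &&
            any(diff(sub$pos) > object@maxDistance))
            return("consecutive group members exceed maxDistance")
    }
    TRUE
})

#' @describeIn CandidateGroups number of groups.
#' @param x a `CandidateGroups`.
#' @export
setMethod("length", "CandidateGroups", function(x) length(x@groups))

#' Member indices of candidate groups
#' @param x a [CandidateGroups-class].
#' @return list of integer row-index vectors into `indelRecords(indels(x))`.
#' @export
groupMembers <- function(x) {
    stopifnot(is(x, "CandidateGroups"))
    x@groups
}

#' Input indels behind a CandidateGroups or RedundancyReport
#' @param x a [CandidateGroups-class] or [RedundancyReport-class].
#' @return the [IndelSet-class] the object was built from.
#' @export
indels <- function(x) {
    stopifnot(is(x, "CandidateGroups") || is(x, "RedundancyReport"))
    x@indels
}

#' @export
#' @describeIn groupMembers per-group metadata table (one row per group).
groupTable <- function(x) {
    stopifnot(is(x, "CandidateGroups"))
    df <- indelRecords(x@indels)
    if (length(x@groups) == 0L)
        return(data.frame(group_id = integer(), chrom = character(),
                          type = character(), length = integer(),
                          size = integer(), first_pos = integer()))
    firsts <- vapply(x@groups, `[`, integer(1), 1L)
    data.frame(
        group_id = seq_along(x@groups) - 1L,
        chrom = df$chrom[firsts],
        type = df$type[firsts],
        length = df$length[firsts],
        size = lengths(x@groups),
        first_pos = df$pos[firsts]
    )
}

#' @export
setMethod("show", "CandidateGroups", function(object) {
    cat("CandidateGroups:", length(object@groups), "groups (D =",
        object@maxDistance, "bp) over", length(object@indels), "indels;",
        pairCount(object), "candidate pairs\n")
    invisible(NULL)
})

#' RedundancyReport: equivalence clusters and redundancy rates
#'
#' Result of [detectRedundancy()] / [summarizeRedundancy()]. Each cluster
#' is a set of indel annotations that produce the identical mutated
#' chromosome; its representative is the member with the smallest position
#' (ties broken by id). The redundant count is the number of annotations
#' that could be removed, i.e. sum over clusters of (size - 1).
#'
#' @slot indels the full analysed `IndelSet`.
#' @slot clusters list of integer vectors of row indices, one per cluster.
#' @slot representatives integer vector, the representative row per cluster.
#' @slot maxDistance distance threshold D used for candidate grouping.
#' @slot summary per-scope totals: rows `total`, `INS`, `DEL` with columns
#'   `n`, `redundant`, `rate` (proportion in `[0, 1]`).
#' @exportClass RedundancyReport
setClass("RedundancyReport", representation(
    indels = "IndelSet", clusters = "list", representatives = "integer",
    maxDistance = "integer", summary = "data.frame"))

setValidity("RedundancyReport", function(object) {
    s <- object@summary
    if (!all(c("scope", "n", "redundant", "rate") %in% names(s)))
        return("summary must have columns scope, n, redundant, rate")
    if (any(s$redundant > s$n)) return("redundant cannot exceed total")
    if (any(s$rate < 0 | s$rate > 1)) return("rate must lie in [0, 1]")
    if (length(object@representatives) != length(object@clusters))
        return("one representative per cluster required")
    ok <- mapply(function(r, cl) r %in% cl,
                 object@representatives, object@clusters)
    if (length(ok) && !all(ok))
        return("representative must be a cluster member")
    TRUE
})

#' @describeIn RedundancyReport number of clusters.
#' @param x a `RedundancyReport`.
#' @export
setMethod("length", "RedundancyReport", function(x) length(x@clusters))

#' Summary table of a RedundancyReport
#' @param x a [RedundancyReport-class].
#' @return data.frame with rows `total`, `INS`, `DEL`.
#' @export
redundancySummary <- function(x) {
    stopifnot(is(x, "RedundancyReport"))
    x@summary
}

#' Redundancy rate from a report
#' @param x a [RedundancyReport-class].
#' @param scope one of `"total"`, `"INS"`, `"DEL"`.
#' @return the redundancy rate as a proportion.
#' @export
redundancyRate <- function(x, scope = c("total", "INS", "DEL")) {
    stopifnot(is(x, "RedundancyReport"))
    scope <- match.arg(scope)
    x@summary$rate[x@summary$scope == scope]
}

#' Member-level cluster table
#'
#' @param x a [RedundancyReport-class].
#' @return data.frame with one row per cluster member: `cluster_id`,
#'   `representative_id`, `member_id`, `chrom`, `type`, `length`, `pos`.
#' @export
clusterTable <- function(x) {
    stopifnot(is(x, "RedundancyReport"))
    df <- indelRecords(x@indels)
    if (length(x@clusters) == 0L)
        return(data.frame(cluster_id = integer(),
                          representative_id = character(),
                          member_id = character(), chrom = character(),
                          type = character(), length = integer(),
                          pos = integer()))
    rows <- do.call(rbind, lapply(seq_along(x@clusters), function(k) {
        m <- x@clusters[[k]]
        data.frame(
            cluster_id = k - 1L,
            representative_id = df$id[x@representatives[k]],
            member_id = df$id[m],
            chrom = df$chrom[m],
            type = df$type[m],
            length = df$length[m],
            pos = df$pos[m]
        )
    }))
    rownames(rows) <- NULL
    rows
}

#' Non-redundant record set from a report
#'
#' Keeps the representative of each cluster plus every unclustered record.
#'
#' @param x a [RedundancyReport-class].
#' @return an [IndelSet-class] with redundant annotations removed.
#' @export
nonRedundant <- function(x) {
    stopifnot(is(x, "RedundancyReport"))
    drop <- setdiff(unlist(x@clusters), x@representatives)
    keep <- setdiff(seq_len(length(x@indels)), drop)
    x@indels[keep]
}

#' @export
setMethod("show", "RedundancyReport", function(object) {
    s <- object@summary
    tot <- s[s$scope == "total", ]
    cat("RedundancyReport (D =", object@maxDistance, "bp):",
        tot$n, "indels,", length(object@clusters), "clusters,",
        tot$redundant, "redundant",
        sprintf("(%.2f%%)\n", 100 * tot$rate))
    for (sc in c("INS", "DEL")) {
        r <- s[s$scope == sc, ]
        cat(sprintf("  %s: %d / %d redundant (%.2f%%)\n",
                    sc, r$redundant, r$n, 100 * r$rate))
    }
    invisible(NULL)
})

#' FitResult: a fitted distribution family
#'
#' @slot family one of `"pareto"`, `"gamma"`, `"exponential"`, `"weibull"`.
#' @slot estimate named numeric parameter estimates (`shape` for Pareto
#'   with location fixed at 1; `shape`/`rate` for Gamma; `rate` for
#'   exponential; `shape`/`scale` for Weibull).
#' @slot n sample size.
#' @slot logLik total log-likelihood of the sample at the estimate.
#' @exportClass FitResult
setClass("FitResult", representation(
    family = "character", estimate = "numeric", n = "integer",
    logLik = "numeric"))

setValidity("FitResult", function(object) {
    if (!object@family %in% c("pareto", "gamma", "exponential", "weibull"))
        return("unknown family")
    if (any(!is.finite(object@estimate)) || any(object@estimate <= 0))
        return("estimates must be strictly positive and finite")
    if (!is.finite(object@logLik)) return("logLik must be finite")
    TRUE
})

#' Parameter estimates of a FitResult
#' @param x a [FitResult-class].
#' @return named numeric vector of estimates.
#' @export
fitEstimate <- function(x) {
    stopifnot(is(x, "FitResult"))
    x@estimate
}

#' Distribution family of a FitResult
#' @param x a [FitResult-class].
#' @return character scalar family name.
#' @export
fitFamily <- function(x) {
    stopifnot(is(x, "FitResult"))
    x@family
}

#' @export
setMethod("logLik", "FitResult", function(object, ...) {
    structure(object@logLik, df = length(object@estimate),
              nobs = object@n, class = "logLik")
})

#' @export
setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s] n = %d, logLik = %.6g\n",
                object@family, object@n, object@logLik))
    print(object@estimate)
    invisible(NULL)
})
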