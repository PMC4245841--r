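.one_record <- function(x) {
    if (is(x, "IndelSet")) {
        stopifnot(length(x) == 1L)
        return(indelRecords(x)[1L, ])
    }
    stopifnot(is.data.frame(x) || is.list(x))
    as.list(x)
}

#' Build the template and variant substrings for an indel pair
#'
#' For two same-type, same-length indels A and B on one chromosome with
#' `pos(A) <= pos(B)`, the redundancy decision only needs the local
#' reference segment between them. For insertions the template is the
#' reference from A's position up to the base before B's position (empty
#' when the positions coincide); A's variant is its allele prepended to
#' the template, B's is its allele appended. For deletions the template
#' runs from A's first deleted base through B's last deleted base; A's
#' variant removes the first L characters, B's removes the last L. The
#' pair is redundant iff the two variant substrings are identical — which
#' is provably equivalent to comparing the two full mutated chromosomes
#' (see [applyIndel()]).
#'
#' @param a,b single indel records (one-row [IndelSet-class], one-row
#'   data.frame, or list with `chrom`, `pos`, `type`, `allele`, `length`).
#'   Must share chromosome, type and length; for deletions both alleles
#'   must match the reference at their positions.
#' @param ref a [Biostrings::DNAStringSet].
#' @return list with `template`, `vA`, `vB`.
#' @export
variantPair <- function(a, b, ref) {
    a <- .one_record(a); b <- .one_record(b)
    if (a$chrom != b$chrom) stop("records are on different chromosomes")
    if (a$type != b$type) stop("records differ in type")
    if (a$length != b$length) stop("records differ in length")
    if (a$pos > b$pos) { tmp <- a; a <- b; b <- tmp }
    L <- a$length
    if (a$type == "INS") {
        template <- if (a$pos == b$pos) "" else
            refSlice(ref, a$chrom, a$pos, b$pos - 1L)
        list(template = template,
             vA = paste0(a$allele, template),
             vB = paste0(template, b$allele))
    } else {
        template <- refSlice(ref, a$chrom, a$pos, b$pos + L - 1L)
        if (substr(template, 1L, L) != a$allele)
            stop("deletion allele of record at pos ", a$pos,
                 " does not match the reference; validate deletions first")
        n <- nchar(template)
        if (substr(template, n - L + 1L, n) != b$allele)
            stop("deletion allele of record at pos ", b$pos,
                 " does not match the reference; validate deletions first")
        list(template = template,
             vA = substring(template, L + 1L),
             vB = substr(template, 1L, n - L))
    }
}

#' Are two indel annotations redundant?
#'
#' `TRUE` iff the two records produce the identical mutated chromosome.
#' Decided locally via [variantPair()]; records of mismatched chromosome,
#' type or length are non-redundant without any string work.
#'
#' @inheritParams variantPair
#' @return logical scalar.
#' @export
pairRedundant <- function(a, b, ref) {
    ra <- .one_record(a); rb <- .one_record(b)
    if (ra$chrom != rb$chrom || ra$type != rb$type ||
        ra$length != rb$length) return(FALSE)
    vp <- variantPair(ra, rb, ref)
    vp$vA == vp$vB
}

#' Apply one indel to the reference (full-sequence oracle)
#'
#' Returns the entire mutated chromosome: an insertion places the allele
#' immediately before the base at `pos`; a deletion removes
#' `[pos, pos + L - 1]`. This is the definitional route to redundancy —
#' two annotations are redundant iff their mutated chromosomes are equal —
#' kept independent of the template shortcut so each can verify the other.
#'
#' @param indel a single indel record (as in [variantPair()]).
#' @param ref a [Biostrings::DNAStringSet].
#' @return character scalar, the mutated chromosome sequence.
#' @export
applyIndel <- function(indel, ref) {
    r <- .one_record(indel)
    s <- as.character(ref[[r$chrom]])
    n <- nchar(s)
    if (r$type == "INS") {
        if (r$pos > n + 1L)
            stop("insertion point ", r$pos, " beyond chromosome end")
        paste0(substr(s, 1L, r$pos - 1L), r$allele, substr(s, r$pos, n))
    } else {
        end <- r$pos + r$length - 1L
        if (end > n)
            stop("deletion window [", r$pos, ", ", end,
                 "] beyond chromosome end")
        if (substr(s, r$pos, end) != r$allele)
            stop("deletion allele '", r$allele,
                 "' does not match reference at ", r$chrom, ":", r$pos)
        paste0(substr(s, 1L, r$pos - 1L), substr(s, end + 1L, n))
    }
}

# union-find with path compression; parent is an integer vector
.uf_find <- function(parent, i) {
    while (parent[i] != i) i <- parent[i]
    i
}

#' Cluster redundant indels within candidate groups
#'
#' Every unordered pair inside each candidate group is tested with
#' [pairRedundant()]; redundant pairs are merged into connected
#' components. Because redundancy is equality of mutated sequences it is
#' transitive, so components are genuine equivalence classes. Components
#' of size >= 2 are returned in `(chrom, representative position,
#' representative id)` order; the representative of a cluster is its
#' member with the smallest position (ties: smallest id).
#'
#' @param groups a [CandidateGroups-class].
#' @param ref a [Biostrings::DNAStringSet].
#' @return list of integer vectors of row indices into
#'   `indelRecords(indels(groups))`, one per cluster, each sorted.
#' @export
findClusters <- function(groups, ref) {
    stopifnot(is(groups, "CandidateGroups"))
    df <- indelRecords(groups@indels)
    # per-chromosome plain strings so pair tests don't re-decode
    clusters <- list()
    for (g in groupMembers(groups)) {
        m <- length(g)
        parent <- seq_len(m)
        for (i in seq_len(m - 1L)) {
            for (j in seq.int(i + 1L, m)) {
                ri <- .uf_find(parent, i)
                rj <- .uf_find(parent, j)
                if (ri == rj) next
                ok <- tryCatch(
                    pairRedundant(df[g[i], ], df[g[j], ], ref),
                    error = function(e) stop(
                        "redundancy check failed for pair ('", df$id[g[i]],
                        "', '", df$id[g[j]], "'): ", conditionMessage(e)))
                if (ok) parent[rj] <- ri
            }
        }
        roots <- vapply(seq_len(m), function(i) .uf_find(parent, i),
                        integer(1))
        for (comp in split(seq_len(m), roots)) {
            if (length(comp) >= 2L)
                clusters[[length(clusters) + 1L]] <- sort(g[comp])
        }
    }
    if (length(clusters) == 0L) return(list())
    # representative = member with min pos then min id; rows are sorted by
    # (chrom, pos, id) globally so the smallest row index is the representative
    reps <- vapply(clusters, min, integer(1))
    ord <- order(df$chrom[reps], df$pos[reps], df$id[reps])
    clusters[ord]
}

#' Summarise redundancy clusters into a report
#'
#' The redundant count is the number of removable annotations: for each
#' cluster, all members but one. Rates are reported overall and per type.
#'
#' @param clusters list of clusters from [findClusters()].
#' @param x the [IndelSet-class] the clusters were computed over.
#' @param maxDistance the distance threshold D used for grouping.
#' @return a [RedundancyReport-class].
#' @export
summarizeRedundancy <- function(clusters, x, maxDistance = 100L) {
    stopifnot(is(x, "IndelSet"))
    df <- indelRecords(x)
    reps <- vapply(clusters, min, integer(1))
    clType <- if (length(clusters)) df$type[reps] else character(0)
    clSize <- lengths(clusters)
    scopes <- c("total", "INS", "DEL")
    summary <- do.call(rbind, lapply(scopes, function(sc) {
        inScope <- if (sc == "total") rep(TRUE, nrow(df)) else df$type == sc
        clIn <- if (sc == "total") rep(TRUE, length(clusters)) else clType == sc
        n <- sum(inScope)
        red <- sum(clSize[clIn] - 1L)
        data.frame(scope = sc, n = n, redundant = as.integer(red),
                   rate = if (n == 0L) 0 else red / n)
    }))
    rownames(summary) <- NULL
    new("RedundancyReport", indels = x, clusters = clusters,
        representatives = reps, maxDistance = as.integer(maxDistance),
        summary = summary)
}

#' Full redundancy detection pipeline
#'
#' Convenience wrapper: [candidateGroups()] then [findClusters()] then
#' [summarizeRedundancy()].
#'
#' @param x an [IndelSet-class] (deletions should be validated against the
#'   reference first; see [validateDeletions()]).
#' @param ref a [Biostrings::DNAStringSet].
#' @param maxDistance distance threshold D in base pairs.
#' @return a [RedundancyReport-class].
#' @export
detectRedundancy <- function(x, ref, maxDistance = 100L) {
    groups <- candidateGroups(x, maxDistance)
    clusters <- findClusters(groups, ref)
    summarizeRedundancy(clusters, x, maxDistance)
}

#' Redundancy as a function of the distance threshold
#'
#' Runs the full pipeline at each threshold and tabulates counts and
#' rates. The redundant count is non-decreasing in D: growing the
#' threshold can only merge more records into candidate groups.
#'
#' @param x an [IndelSet-class].
#' @param ref a [Biostrings::DNAStringSet].
#' @param distances integer vector of thresholds (default the standard
#'   grid `c(1, 5, 10, 100)`).
#' @return data.frame with one row per threshold: `max_distance`, `n`,
#'   `redundant_total`, `redundant_ins`, `redundant_del`, `rate_total`,
#'   `rate_ins`, `rate_del`.
#' @export
redundancySweep <- function(x, ref, distances = c(1L, 5L, 10L, 100L)) {
    stopifnot(length(distances) >= 1L)
    rows <- lapply(sort(as.integer(distances)), function(D) {
        rep <- detectRedundancy(x, ref, D)
        s <- redundancySummary(rep)
        v <- function(scope, col) s[s$scope == scope, col]
        data.frame(max_distance = D, n = v("total", "n"),
                   redundant_total = v("total", "redundant"),
                   redundant_ins = v("INS", "redundant"),
                   redundant_del = v("DEL", "redundant"),
                   rate_total = v("total", "rate"),
                   rate_ins = v("INS", "rate"),
                   rate_del = v("DEL", "rate"))
    })
    do.call(rbind, rows)
}
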