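#' Chain indels into candidate redundant groups
#'
#' Indels of different type or length can never be redundant, so records
#' are first partitioned by `(chrom, type, length)`. Within each
#' partition, records sorted by position are chained: a record joins the
#' current group when its position is at most `maxDistance` base pairs
#' after the previous member (ties at distance 0 always co-group). Groups
#' of size 1 are discarded — a candidate redundant group needs at least
#' two members — and the trailing group is flushed. Group ids are
#' sequential from 0 in `(chrom, type, length, first position)` order, so
#' the output is deterministic.
#'
#' @param x an [IndelSet-class]; may span multiple chromosomes.
#' @param maxDistance the distance threshold D in base pairs (default 100,
#'   the cutoff at which the redundancy yield flattens out on real
#'   catalogues).
#' @return a [CandidateGroups-class].
#' @export
candidateGroups <- function(x, maxDistance = 100L) {
    stopifnot(is(x, "IndelSet"))
    maxDistance <- as.integer(maxDistance)
    if (is.na(maxDistance) || maxDistance < 0L)
        stop("maxDistance must be a non-negative integer")
    df <- indelRecords(x)
    groups <- list()
    if (nrow(df) > 0L) {
        key <- paste(df$chrom, df$type, df$length, sep = "\r")
        idx <- split(seq_len(nrow(df)), key)
        firsts <- vapply(idx, `[`, integer(1), 1L)
        ord <- order(df$chrom[firsts], df$type[firsts], df$length[firsts])
        for (part in idx[ord]) {
            # rows already sorted by (chrom, pos, id) within the partition
            current <- part[1L]
            for (i in part[-1L]) {
                if (df$pos[i] - df$pos[current[length(current)]] <= maxDistance) {
                    current <- c(current, i)
                } else {
                    if (length(current) >= 2L) groups[[length(groups) + 1L]] <- current
                    current <- i
                }
            }
            if (length(current) >= 2L) groups[[length(groups) + 1L]] <- current
        }
    }
    new("CandidateGroups", indels = x, groups = groups,
        maxDistance = maxDistance)
}

#' Number of within-group pairs
#'
#' The pairwise redundancy check tests every unordered pair inside each
#' candidate group; this is the total work estimate, sum of
#' `m * (m - 1) / 2` over group sizes m.
#'
#' @param x a [CandidateGroups-class].
#' @return integer pair count.
#' @export
pairCount <- function(x) {
    stopifnot(is(x, "CandidateGroups"))
    m <- lengths(x@groups)
    as.integer(sum(m * (m - 1) / 2))
}
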