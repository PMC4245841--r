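makeRef <- function(...) {
    Biostrings::DNAStringSet(c(...))
}

writeTempFasta <- function(lines) {
    path <- withr::local_tempfile(fileext = ".fa",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

writeTempLines <- function(lines, ext = ".tsv") {
    path <- withr::local_tempfile(fileext = ext,
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

vcfHeader <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
)

# random valid same-type same-length indel pair on a reference; deletion
# alleles are copied from the reference so both routes are defined
randomValidPair <- function(ref, chrom, maxGap = 60L) {
    L <- redundel::chromLengths(ref)[[chrom]]
    len <- sample(1:4, 1L)
    type <- sample(c("INS", "DEL"), 1L)
    posA <- sample.int(L - maxGap - len - 2L, 1L) + 1L
    posB <- posA + sample(0:maxGap, 1L)
    if (type == "DEL") {
        alA <- refSlice(ref, chrom, posA, posA + len - 1L)
        alB <- refSlice(ref, chrom, posB, posB + len - 1L)
    } else {
        # bias toward potentially redundant cases: half the time reuse
        # the reference context as the inserted allele
        mk <- function(p) if (runif(1) < 0.5)
            refSlice(ref, chrom, p, p + len - 1L)
        else paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
        alA <- mk(posA)
        alB <- if (runif(1) < 0.5) alA else mk(posB)
    }
    list(a = list(id = "a", chrom = chrom, pos = posA, type = type,
                  allele = alA, length = len),
         b = list(id = "b", chrom = chrom, pos = posB, type = type,
                  allele = alB, length = len))
}

# independent clustering route: within candidate groups, group members by
# their full mutated chromosome string (sequence equality IS redundancy)
oracleClusters <- function(x, ref, maxDistance = 100L) {
    groups <- candidateGroups(x, maxDistance)
    df <- indelRecords(x)
    out <- list()
    for (g in groupMembers(groups)) {
        muts <- vapply(g, function(i) applyIndel(df[i, ], ref), character(1))
        for (comp in split(g, muts))
            if (length(comp) >= 2L) out[[length(out) + 1L]] <- sort(comp)
    }
    out
}

# canonical string form of a cluster list for set comparison
clusterKey <- function(clusters, x) {
    df <- indelRecords(x)
    sort(vapply(clusters, function(v)
        paste(sort(df$id[v]), collapse = ","), character(1)))
}
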