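rec <- function(pos, type, allele, chrom = "chr1", id = "x") {
    list(id = id, chrom = chrom, pos = as.integer(pos), type = type,
         allele = allele, length = nchar(allele))
}

test_that("variant substrings follow the template construction", {
    ref <- makeRef(chr1 = "GCACACAG")
    vp <- variantPair(rec(2, "INS", "CA"), rec(4, "INS", "CA"), ref)
    expect_equal(vp$template, "CA")
    expect_equal(vp$vA, "CACA")
    expect_equal(vp$vB, "CACA")

    ref2 <- makeRef(chr1 = "TTAAAATT")
    vp2 <- variantPair(rec(3, "DEL", "A"), rec(6, "DEL", "A"), ref2)
    expect_equal(vp2$template, "AAAA")
    expect_equal(vp2$vA, "AAA")
    expect_equal(vp2$vB, "AAA")

    # degenerate: identical positions give an empty INS template
    vp3 <- variantPair(rec(5, "INS", "GG"), rec(5, "INS", "GG"), ref)
    expect_equal(vp3$template, "")
    expect_equal(vp3$vA, "GG")
    expect_equal(vp3$vB, "GG")

    # size invariants: |v| = |template| + L (INS), |template| - L (DEL)
    expect_equal(nchar(vp$vA), nchar(vp$template) + 2L)
    expect_equal(nchar(vp2$vA), nchar(vp2$template) - 1L)

    expect_error(variantPair(rec(2, "INS", "CA"), rec(4, "DEL", "CA"), ref),
                 "type")
    expect_error(variantPair(rec(2, "INS", "C"), rec(4, "INS", "CA"), ref),
                 "length")
    expect_error(
        variantPair(rec(2, "DEL", "CA"),
                    rec(8, "DEL", "AG"), makeRef(chr1 = "GCACACAG")),
        "out of bounds")
})

test_that("pair redundancy is exact variant-string equality", {
    ref <- makeRef(chr1 = "GCACACAG")
    expect_true(pairRedundant(rec(2, "INS", "CA"), rec(4, "INS", "CA"), ref))
    ref2 <- makeRef(chr1 = "ACGT")
    expect_false(pairRedundant(rec(2, "DEL", "C"), rec(3, "DEL", "G"), ref2))
    # reflexivity
    r <- rec(3, "DEL", "G", id = "self")
    expect_true(pairRedundant(r, r, ref2))
    # symmetry: argument order does not matter
    a <- rec(2, "INS", "CA"); b <- rec(4, "INS", "CA")
    expect_equal(pairRedundant(a, b, ref), pairRedundant(b, a, ref))
    # mismatched type/length is non-redundant without error
    expect_false(pairRedundant(rec(2, "INS", "C"), rec(2, "DEL", "C"), ref))
    expect_false(pairRedundant(rec(2, "INS", "C"), rec(2, "INS", "CC"), ref))
})

test_that("the full-sequence oracle applies indels correctly", {
    ref <- makeRef(chr1 = "ACGT")
    expect_equal(applyIndel(rec(3, "INS", "TT"), ref), "ACTTGT")
    expect_equal(applyIndel(rec(2, "DEL", "CG"), ref), "AT")
    expect_error(applyIndel(rec(2, "DEL", "GG"), ref), "does not match")
    # insertion before position 1 and at chromosome end + 1
    expect_equal(applyIndel(rec(1, "INS", "G"), ref), "GACGT")
    expect_equal(applyIndel(rec(5, "INS", "G"), ref), "ACGTG")
    expect_error(applyIndel(rec(7, "INS", "G"), ref), "beyond")

    # delete then re-insert the same allele restores the reference
    mut <- applyIndel(rec(2, "DEL", "CG"), ref)
    back <- applyIndel(rec(2, "INS", "CG"), makeRef(chr1 = mut))
    expect_equal(back, "ACGT")
})

test_that("template decision equals full-sequence comparison on random pairs", {
    cfg <- simConfig(seed = 202, chromLength = 3000L, repeatDensity = 0.3)
    ref <- simulateReference(cfg)
    chrom <- names(ref)[1]
    set.seed(203)
    agree <- 0L
    nRedundant <- 0L
    for (i in 1:400) {
        p <- randomValidPair(ref, chrom)
        templ <- pairRedundant(p$a, p$b, ref)
        oracle <- identical(applyIndel(p$a, ref), applyIndel(p$b, ref))
        expect_identical(templ, oracle)
        agree <- agree + (templ == oracle)
        nRedundant <- nRedundant + templ
    }
    expect_equal(agree, 400L)
    # the case mix must exercise both outcomes
    expect_gt(nRedundant, 0L)
    expect_lt(nRedundant, 400L)
})

test_that("clusters are connected components, deterministically ordered", {
    # CACACA tract: unit insertions at 3, 5, 7 are pairwise redundant
    ref <- makeRef(chr1 = "GGCACACATT")
    x <- IndelSet(c("a", "b", "c"), "chr1", c(3L, 5L, 7L), "INS", "CA")
    cl <- findClusters(candidateGroups(x, 100L), ref)
    expect_length(cl, 1L)
    expect_length(cl[[1]], 3L)

    # group of two non-redundant indels yields nothing
    ref2 <- makeRef(chr1 = "ACGTACGT")
    x2 <- IndelSet(c("a", "b"), "chr1", c(2L, 5L), "INS", "TT")
    expect_length(findClusters(candidateGroups(x2, 100L), ref2), 0L)

    # two disjoint redundant pairs inside one candidate group
    ref3 <- makeRef(chr1 = "GGCACATTTTGTGTAA")
    x3 <- IndelSet(c("a", "b", "c", "d"), "chr1",
                   c(3L, 5L, 11L, 13L), "INS",
                   c("CA", "CA", "GT", "GT"))
    g3 <- candidateGroups(x3, 100L)
    expect_equal(length(g3), 1L)     # all four chain into one group
    cl3 <- findClusters(g3, ref3)
    expect_length(cl3, 2L)
    expect_equal(lengths(cl3), c(2L, 2L))

    # input order permutation does not change the clusters
    perm <- IndelSet(c("d", "b", "a", "c"), "chr1",
                     c(13L, 5L, 3L, 11L), "INS",
                     c("GT", "CA", "CA", "GT"))
    cl3p <- findClusters(candidateGroups(perm, 100L), ref3)
    expect_equal(clusterKey(cl3, x3), clusterKey(cl3p, perm))
})

test_that("summaries count removable annotations per type", {
    x <- IndelSet(sprintf("r%02d", 1:10), "chr1",
                  seq(10L, 100L, 10L), rep(c("INS", "DEL"), 5), "A")
    rep1 <- summarizeRedundancy(list(c(1L, 3L, 5L), c(2L, 4L)), x, 100L)
    s <- redundancySummary(rep1)
    expect_equal(s$redundant[s$scope == "total"], 3L)
    expect_equal(redundancyRate(rep1, "total"), 0.3)
    expect_equal(s$n[s$scope == "INS"] + s$n[s$scope == "DEL"],
                 s$n[s$scope == "total"])

    # no clusters: all rates zero
    rep0 <- summarizeRedundancy(list(), x, 100L)
    expect_equal(redundancyRate(rep0, "total"), 0)

    # all n records in one cluster: rate (n-1)/n
    xIns <- IndelSet(sprintf("q%02d", 1:10), "chr1",
                     seq(10L, 100L, 10L), "INS", "A")
    repAll <- summarizeRedundancy(list(1:10), xIns, 100L)
    expect_equal(redundancyRate(repAll, "total"), 0.9)

    # representatives are min-pos members; nonRedundant keeps them
    nr <- nonRedundant(rep1)
    expect_true(all(c("r01", "r02") %in% indelRecords(nr)$id))
    expect_equal(length(nr), 10L - 3L)
})

test_that("redundant counts never decrease as D grows", {
    for (seed in c(31, 32, 33)) {
        cfg <- simConfig(seed = seed, chromLength = 30000L, nIndels = 60L)
        ref <- simulateReference(cfg)
        truth <- simulateIndels(ref, cfg)
        sw <- redundancySweep(truth$indels, ref, c(1L, 5L, 10L, 100L))
        expect_true(!is.unsorted(sw$redundant_total))
        expect_true(!is.unsorted(sw$redundant_ins))
        expect_true(!is.unsorted(sw$redundant_del))
    }
})
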