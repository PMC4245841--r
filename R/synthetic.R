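#' Simulation configuration
#'
#' Bundles the parameters of the synthetic reference + indel generator.
#' The distributional defaults are the genome-wide values estimated from
#' large human indel catalogues: Pareto(location 1) sizes with shape 1.43,
#' and Gamma(shape 0.4, rate 8.09e-4) inter-indel distances (mean ~494 bp).
#'
#' @param seed integer seed; mandatory, all generation is deterministic
#'   per seed.
#' @param chromLength chromosome length in bp.
#' @param repeatDensity proportion of the sequence covered by planted
#'   repeat tracts (homopolymers and di-/tri-nucleotide tandem repeats).
#' @param nIndels total number of indel annotations to emit.
#' @param plantedRedundancyRate planted proportion of redundant
#'   annotations, i.e. sum over planted classes of (size - 1) divided by
#'   `nIndels`.
#' @param paretoShape shape of the Pareto size distribution (location 1).
#' @param gammaShape,gammaRate Gamma parameters for inter-indel gaps.
#' @param maxClusterSpan maximum distance between any two annotations of
#'   one planted equivalence class; keep at or below the analysis
#'   threshold D so planted classes are recoverable.
#' @param chromName name of the simulated chromosome.
#' @return a validated list of class `simConfig`.
#' @export
simConfig <- function(seed,
                      chromLength = 100000L,
                      repeatDensity = 0.2,
                      nIndels = 100L,
                      plantedRedundancyRate = 0.1,
                      paretoShape = 1.43,
                      gammaShape = 0.4,
                      gammaRate = 8.09e-4,
                      maxClusterSpan = 100L,
                      chromName = "simChr") {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- list(seed = as.integer(seed),
                chromLength = as.integer(chromLength),
                repeatDensity = repeatDensity,
                nIndels = as.integer(nIndels),
                plantedRedundancyRate = plantedRedundancyRate,
                paretoShape = paretoShape,
                gammaShape = gammaShape,
                gammaRate = gammaRate,
                maxClusterSpan = as.integer(maxClusterSpan),
                chromName = chromName)
    stopifnot(cfg$chromLength > 0L, cfg$nIndels >= 0L,
              cfg$repeatDensity >= 0, cfg$repeatDensity <= 1,
              cfg$plantedRedundancyRate >= 0,
              cfg$plantedRedundancyRate <= 1,
              cfg$paretoShape > 0, cfg$gammaShape > 0, cfg$gammaRate > 0,
              cfg$maxClusterSpan >= 1L)
    class(cfg) <- c("simConfig", "list")
    cfg
}

#' Simulate a repeat-rich reference chromosome
#'
#' Generates an i.i.d. A/C/G/T sequence and plants non-overlapping repeat
#' tracts (homopolymers of 4-12 copies; di- and tri-nucleotide tandem
#' repeats of 3-8 copies) until `repeatDensity` of the sequence is
#' covered. The tract table (start, period, copies, unit) is attached as
#' `metadata(ref)$repeats` for the indel planter. Identical seeds give
#' byte-identical sequences.
#'
#' @param config a [simConfig()].
#' @return a [Biostrings::DNAStringSet] of length 1 with tract metadata.
#' @export
simulateReference <- function(config) {
    stopifnot(inherits(config, "simConfig"))
    if (config$repeatDensity > 0.6)
        stop("repeatDensity above 0.6 is not achievable with ",
             "non-overlapping tract placement")
    set.seed(config$seed)
    L <- config$chromLength
    seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    occupied <- logical(L)
    target <- round(config$repeatDensity * L)
    planted <- 0L
    tracts <- list()
    attempts <- 0L
    while (planted < target) {
        attempts <- attempts + 1L
        if (attempts > 200L * max(1L, target))
            stop("repeatDensity ", config$repeatDensity,
                 " not achievable on a chromosome of length ", L)
        p <- sample(1:3, 1L)
        copies <- if (p == 1L) sample(4:12, 1L) else sample(3:8, 1L)
        len <- p * copies
        if (len > L) next
        start <- sample.int(L - len + 1L, 1L)
        span <- max(1L, start - 1L):min(L, start + len)  # 1 bp buffer
        if (any(occupied[span])) next
        unit <- paste(sample(c("A", "C", "G", "T"), p, replace = TRUE),
                      collapse = "")
        seqv[start:(start + len - 1L)] <-
            rep(strsplit(unit, "")[[1L]], copies)
        occupied[span] <- TRUE
        planted <- planted + len
        tracts[[length(tracts) + 1L]] <- data.frame(
            start = start, end = start + len - 1L,
            period = p, copies = copies, unit = unit)
    }
    ref <- DNAStringSet(setNames(paste(seqv, collapse = ""),
                                 config$chromName))
    metadata(ref)$repeats <- if (length(tracts))
        do.call(rbind, tracts) else
        data.frame(start = integer(), end = integer(), period = integer(),
                   copies = integer(), unit = character())
    ref
}

#' Draw i.i.d. samples from one of the supported families
#'
#' Pareto(location 1) uses the inverse CDF `(1 - u)^(-1/shape)`; the other
#' families use R's standard samplers. Deterministic per seed.
#'
#' @param family `"pareto"`, `"gamma"`, `"exponential"` or `"weibull"`.
#' @param params named list/vector: `shape` for pareto; `shape`, `rate`
#'   for gamma; `rate` for exponential; `shape`, `scale` for weibull.
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sampleDistribution <- function(family, params, n, seed) {
    stopifnot(n >= 1L)
    params <- as.list(params)
    set.seed(seed)
    switch(family,
           pareto = (1 - runif(n))^(-1 / params$shape),
           gamma = rgamma(n, shape = params$shape, rate = params$rate),
           exponential = rexp(n, rate = params$rate),
           weibull = rweibull(n, shape = params$shape,
                              scale = params$scale),
           stop("unknown family: '", family, "'"))
}

# split planted redundancy into cluster sizes: sum(size - 1) == nRed and
# sum(size) <= nMembersMax; pairs preferred, merged when members run out
.cluster_sizes <- function(nRed, nMembersMax) {
    if (nRed == 0L) return(integer(0))
    sizes <- rep(2L, nRed)
    while (sum(sizes) > nMembersMax && length(sizes) >= 2L) {
        # merging clusters of sizes a and b into a + b - 1 preserves the
        # redundant count and frees one member slot
        sizes <- c(sizes[-(1:2)], sizes[1L] + sizes[2L] - 1L)
    }
    if (sum(sizes) > nMembersMax)
        stop("planted redundancy rate infeasible for ", nMembersMax,
             " records")
    sort(sizes, decreasing = TRUE)
}

#' Simulate indel annotations with planted equivalence classes
#'
#' Background (non-redundant) indels are placed at Gamma-spaced positions
#' outside repeat tracts, with Pareto-distributed sizes (rounded up, so
#' the minimum size is exactly 1); deletion alleles are copied from the
#' reference and are therefore always valid. A `plantedRedundancyRate`
#' fraction of annotations is emitted as extra, equivalent annotations of
#' the same underlying mutation: within a tandem-repeat tract, the same
#' unit insertion (or deletion) is slid along the tract one period at a
#' time, which is exactly the ambiguity that makes alignment-derived
#' annotations redundant. Every planted class is verified equivalent via
#' the full-sequence oracle [applyIndel()] before emission.
#'
#' Background indels may still land in locally repetitive context and form
#' genuine, unplanted equivalences; those are permitted and detectable by
#' the oracle, but are not part of the recorded truth partition.
#'
#' @param ref a reference from [simulateReference()] (tract metadata
#'   required).
#' @param config the same [simConfig()].
#' @return list of class `simTruth`: `indels` (an [IndelSet-class]),
#'   `partition` (list of id vectors, the planted classes of size >= 2),
#'   `expectedRedundant` (sum of class sizes minus class count),
#'   `expectedRate`, `ref`, `config`.
#' @export
simulateIndels <- function(ref, config) {
    stopifnot(inherits(config, "simConfig"))
    tracts <- metadata(ref)$repeats
    if (is.null(tracts)) stop("reference lacks tract metadata")
    L <- Biostrings::width(ref)[1L]
    chrom <- config$chromName
    set.seed(config$seed + 1L)
    nRed <- round(config$plantedRedundancyRate * config$nIndels)
    sizes <- .cluster_sizes(nRed, config$nIndels)
    usable <- tracts[(tracts$copies - 1L) * tracts$period <=
                         config$maxClusterSpan, , drop = FALSE]
    pos <- integer(0); type <- character(0); allele <- character(0)
    truthClass <- integer(0)
    usedTract <- rep(FALSE, nrow(usable))
    usedSpans <- list()
    for (ci in seq_along(sizes)) {
        k <- sizes[ci]
        ok <- which(!usedTract & usable$copies >= k)
        if (length(ok) == 0L)
            stop("cannot place planted class of size ", k,
                 ": no free repeat tract with >= ", k,
                 " copies; increase repeatDensity")
        ti <- ok[sample.int(length(ok), 1L)]
        usedTract[ti] <- TRUE
        tr <- usable[ti, ]
        ty <- sample(c("INS", "DEL"), 1L)
        slots <- tr$start + (seq_len(k) - 1L) * tr$period
        # oracle check: every adjacent pair must mutate identically
        muts <- vapply(slots, function(p) applyIndel(
            list(chrom = chrom, pos = p, type = ty, allele = tr$unit,
                 length = tr$period), ref), character(1))
        if (length(unique(muts)) != 1L)
            stop("internal error: planted class is not equivalent")
        pos <- c(pos, slots)
        type <- c(type, rep(ty, k))
        allele <- c(allele, rep(tr$unit, k))
        truthClass <- c(truthClass, rep(ci, k))
        usedSpans[[length(usedSpans) + 1L]] <- c(tr$start, tr$end)
    }
    nSingle <- config$nIndels - sum(sizes)
    if (nSingle > 0L) {
        # forbid the neighbourhoods of tracts hosting planted classes so
        # background indels cannot slide into them
        forbidden <- logical(L)
        for (sp in usedSpans) {
            lo <- max(1L, sp[1L] - 25L)
            hi <- min(L, sp[2L] + 25L)
            forbidden[lo:hi] <- TRUE
        }
        gaps <- 1L + as.integer(ceiling(
            rgamma(4L * nSingle + 50L, shape = config$gammaShape,
                   rate = config$gammaRate)))
        cand <- cumsum(c(sample.int(200L, 1L), gaps))
        cand <- cand[cand <= L - 30L & cand >= 2L]
        cand <- cand[!forbidden[cand]]
        if (length(cand) < nSingle)
            stop("chromosome too short for ", nSingle,
                 " background indels at the configured gap distribution")
        cand <- cand[seq_len(nSingle)]
        # Pareto(location 1) support is (1, Inf); flooring realises the
        # stated minimum integer size of exactly 1
        szs <- pmin(as.integer(floor(
            sampleDistribution("pareto", list(shape = config$paretoShape),
                               nSingle, config$seed + 2L))), 20L)
        set.seed(config$seed + 3L)
        for (i in seq_len(nSingle)) {
            ty <- sample(c("INS", "DEL"), 1L)
            sz <- szs[i]
            al <- if (ty == "DEL")
                refSlice(ref, chrom, cand[i], cand[i] + sz - 1L)
            else paste(sample(c("A", "C", "G", "T"), sz, replace = TRUE),
                       collapse = "")
            pos <- c(pos, cand[i]); type <- c(type, ty)
            allele <- c(allele, al); truthClass <- c(truthClass, 0L)
        }
    }
    ord <- order(pos, truthClass)
    id <- sprintf("sim%05d", seq_along(pos))
    x <- IndelSet(id, chrom, pos[ord], type[ord], allele[ord])
    truthClass <- truthClass[ord]
    partition <- split(id[truthClass > 0L], truthClass[truthClass > 0L])
    partition <- unname(partition)
    expectedRedundant <- sum(lengths(partition) - 1L)
    out <- list(indels = x, partition = partition,
                expectedRedundant = as.integer(expectedRedundant),
                expectedRate = if (length(x) == 0L) 0 else
                    expectedRedundant / length(x),
                ref = ref, config = config)
    class(out) <- c("simTruth", "list")
    out
}

#' Write a simulated dataset to disk
#'
#' Emits the three artifacts consumed by the pipeline: a FASTA reference,
#' the canonical indel TSV, and a truth JSON recording the planted
#' partition and expected redundant count.
#'
#' @param truth a `simTruth` from [simulateIndels()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths, invisibly.
#' @export
writeSimulation <- function(truth, dir) {
    stopifnot(inherits(truth, "simTruth"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "reference.fa")
    tsv <- file.path(dir, "indels.tsv")
    json <- file.path(dir, "truth.json")
    writeXStringSet(truth$ref, fasta)
    writeIndelTsv(truth$indels, tsv)
    jsonlite::write_json(
        list(seed = truth$config$seed,
             n_indels = length(truth$indels),
             partition = truth$partition,
             expected_redundant = truth$expectedRedundant,
             expected_rate = truth$expectedRate),
        json, auto_unbox = TRUE, digits = NA)
    invisible(c(fasta = fasta, indels = tsv, truth = json))
}
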