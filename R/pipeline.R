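#' Run the redundancy-check pipeline end to end
#'
#' Read (TSV or VCF) -> validate deletions against the reference ->
#' candidate grouping -> pairwise redundancy -> summary, writing the
#' cluster TSV and summary block via [writeReport()]. Per-phase record
#' counts are logged to standard error when `verbose`.
#'
#' @param indelFile canonical indel TSV (exactly one of `indelFile` /
#'   `vcfFile`).
#' @param vcfFile VCF 4.x file with indel records.
#' @param referenceFile FASTA reference.
#' @param maxDistance distance threshold D (default 100).
#' @param outPrefix output path prefix for the report artifacts; `NULL`
#'   skips writing.
#' @param verbose log phase progress to stderr.
#' @return the [RedundancyReport-class], invisibly.
#' @export
runCheck <- function(indelFile = NULL, vcfFile = NULL, referenceFile,
                     maxDistance = 100L, outPrefix = NULL,
                     verbose = FALSE) {
    log <- function(...) if (verbose) message("[check] ", ...)
    if (is.null(indelFile) == is.null(vcfFile))
        .input_error("supply exactly one of indelFile or vcfFile")
    if (missing(referenceFile) || is.null(referenceFile))
        .input_error("a reference FASTA is required")
    ref <- readReference(referenceFile)
    log("reference: ", length(ref), " chromosome(s)")
    x <- if (!is.null(indelFile)) readIndelTsv(indelFile) else {
        v <- readVcfIndels(vcfFile, reference = ref)
        log("VCF: ", v$skipped, " non-indel record(s) skipped")
        v$indels
    }
    log("indels read: ", length(x))
    val <- validateDeletions(x, ref,
                             rejectsPath = if (!is.null(outPrefix))
                                 paste0(outPrefix, "_rejects.tsv") else NULL)
    if (nrow(val$rejects) > 0L)
        log(nrow(val$rejects), " record(s) rejected")
    groups <- candidateGroups(val$pass, maxDistance)
    log("candidate groups: ", length(groups), " (",
        pairCount(groups), " pairs)")
    clusters <- findClusters(groups, ref)
    report <- summarizeRedundancy(clusters, val$pass, maxDistance)
    log("clusters: ", length(clusters), "; redundant: ",
        redundancySummary(report)$redundant[1L])
    if (!is.null(outPrefix)) writeReport(report, outPrefix)
    invisible(report)
}

#' Sweep the distance threshold
#'
#' Runs the full pipeline at each threshold (default grid
#' `c(1, 5, 10, 100)`) and writes one summary row per threshold. Redundant
#' counts are non-decreasing in the threshold.
#'
#' @inheritParams runCheck
#' @param distances integer thresholds.
#' @param outFile optional TSV destination for the sweep table.
#' @return data.frame as from [redundancySweep()], invisibly.
#' @export
runSweep <- function(indelFile = NULL, vcfFile = NULL, referenceFile,
                     distances = c(1L, 5L, 10L, 100L), outFile = NULL,
                     verbose = FALSE) {
    if (is.null(indelFile) == is.null(vcfFile))
        .input_error("supply exactly one of indelFile or vcfFile")
    ref <- readReference(referenceFile)
    x <- if (!is.null(indelFile)) readIndelTsv(indelFile) else
        readVcfIndels(vcfFile, reference = ref)$indels
    x <- validateDeletions(x, ref)$pass
    sweep <- redundancySweep(x, ref, distances)
    if (!is.null(outFile))
        write.table(sweep, outFile, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = TRUE)
    invisible(sweep)
}

#' Fit distribution families to positions or sizes
#'
#' For position input the adjacent distances are formed first. When
#' several families are requested on the same sample their
#' log-likelihoods are directly comparable (same data, MLE each).
#'
#' @param values numeric vector: positions or sizes.
#' @param input `"positions"` (distances are formed via
#'   [adjacentDistances()]) or `"sizes"` / `"distances"` (values used as
#'   is).
#' @param families character vector of families to fit.
#' @param jsonPath optional machine-readable output.
#' @return named list of [FitResult-class] objects, invisibly.
#' @export
runFit <- function(values,
                   input = c("positions", "distances", "sizes"),
                   families = "gamma", jsonPath = NULL) {
    input <- match.arg(input)
    x <- if (input == "positions") adjacentDistances(values) else values
    fits <- lapply(families, function(f)
        tryCatch(fitDistribution(x, f),
                 error = function(e) stop("fit of family '", f,
                                          "' failed: ",
                                          conditionMessage(e))))
    names(fits) <- families
    lines <- formatFits(fits, jsonPath)
    invisible(fits)
}

#' Generate and write a simulated dataset
#'
#' @param config a [simConfig()].
#' @param dir output directory for FASTA + TSV + truth JSON.
#' @return the `simTruth` object, invisibly.
#' @export
runSimulate <- function(config, dir) {
    ref <- simulateReference(config)
    truth <- simulateIndels(ref, config)
    writeSimulation(truth, dir)
    invisible(truth)
}
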