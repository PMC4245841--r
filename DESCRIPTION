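Package: redundel
Title: Detection of Redundant Indel Annotations by Template Substring
    Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinct indel records in variant databases can describe the
    identical change to a reference genome when the indel falls inside a
    repeat tract and equally optimal alignments admit several placements.
    redundel detects such redundant annotations: indels are chained into
    candidate groups by type, length and genomic distance, and each pair
    within a group is tested by comparing variant substrings built from
    the reference template between the two positions. A full-sequence
    mutation oracle verifies the template method. The package also fits
    the distributional models used to characterise indel catalogues
    (Pareto indel sizes; Gamma, exponential and Weibull adjacent-variant
    distances) by maximum likelihood, and ships a seeded simulator that
    plants equivalent indel annotations in repeat-rich synthetic
    references for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
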