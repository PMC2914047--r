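Package: samloo
Title: Two-Color Intron-Exon Array Differential Expression with SAM and
    Leave-One-Out Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for differential expression on combined
    intron-exon two-color oligoarrays: background subtraction and
    expressed calls, LOWESS dye correction, quantile normalization, a
    from-scratch Significance Analysis of Microarrays (SAM) permutation
    statistic with q-values, a patient leave-one-out consensus wrapper,
    classification of probes into protein-coding versus long intronic and
    intergenic non-coding RNA, locus-level coding/ncRNA concordance,
    UPGMA sample clustering, and 2^-ddCT qPCR relative quantification.
    Ships a synthetic-data generator with planted truth so every stage is
    testable without downloads, plus an optional GEO series-matrix reader
    for re-running deposited studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
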