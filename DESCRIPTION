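Package: gcrassay
Title: Fluctuation Analysis and Breakpoint Classification for Yeast
    Gross Chromosomal Rearrangement Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical and sequence-analysis tools for gross chromosomal
    rearrangement (GCR) assays in fission yeast. Estimates GCR rates per
    cell division from Luria-Delbruck fluctuation experiments using the
    Lea-Coulson median estimator with plating-fraction correction, the
    zero-median upper-bound rule, exact order-statistic confidence
    intervals for the median, and two-tailed Mann-Whitney comparisons
    between genotypes. Includes a discrete-generation culture simulator
    for validating the estimator, a classifier for survivor breakpoint
    junctions (de novo telomere addition versus microhomology-mediated
    translocation) with a synthetic-genome generator for round-trip
    testing, and small assay calculators (double point-mutation rate,
    GCR frequency, qPCR cut efficiency, DSB survival rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
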