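Package: imotifr
Title: Scanning, Enrichment and Spectroscopic Analysis of i-Motif DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and characterizing i-motif-forming
    cytosine-rich DNA. Implements a tract/loop folding-rule scanner for
    genomic sequence (four tracts of five or more cytosines separated by
    loops of 1-19 bases, on either strand), promoter-window enrichment
    statistics with chi-squared and Gene Ontology over-representation
    tests under Benjamini-Hochberg false-discovery control, UV
    melting-curve analysis by the first-derivative method (melting and
    annealing temperatures, hysteresis), thermal difference spectrum
    computation and classification, and sigmoidal fitting of circular
    dichroism pH titrations to estimate the transitional pH. Seeded
    synthetic-data generators with known ground truth make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    minpack.lm,
    purrr,
    readr,
    rlang,
    S4Vectors,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
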