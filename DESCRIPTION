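Package: germreprog
Title: Methylome Reprogramming and Small RNA Signatures in Germ Cell Specification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis of whole-genome bisulfite methylation dynamics during
    primordial germ cell specification: tiling- and CpG-count-probe weighted
    methylation quantitation, genomic feature and imprinted-DMR summaries,
    metagene profiles, a background model of global demethylation with
    empirical outlier (escapee) calling, k-means trajectory clustering with
    feature enrichment, repeat-class methylation and RPKM expression, and
    piRNA signature statistics (length spectra, 5' nucleotide composition,
    ping-pong 5'-5' overlap profiles). Includes a deterministic synthetic-data
    generator that emulates stage-wise methylomes with planted kinetic
    classes and slicer-paired small RNA reads, so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
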