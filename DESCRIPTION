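Package: noirseq
Title: Molecular-Barcode Consensus Sequencing with Data-Driven
    Erroneous-Tag Removal and Poisson Variant Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies individual DNA molecules in barcode-tagged amplicon
    sequencing data ('NOIR': non-overlapping integrated reads). Extracts
    random 12-bp (or error-detecting BDHV 15-bp) barcode tags from reads,
    removes erroneous tags with a data-driven reads-per-tag threshold
    derived from 2-read-binned, 11-bin-smoothed correct-length proportions,
    builds one high-fidelity consensus read per accepted molecule, counts
    molecules absolutely, and detects variants de novo with a region-level
    Poisson error model. Includes a synthetic amplicon-library simulator
    with platform-specific error profiles (indel-dominant Ion Torrent,
    substitution-dominant Illumina) and ground-truth logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
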