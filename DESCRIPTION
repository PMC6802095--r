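Package: rrcna
Title: Reduced-Representation Copy-Number Analysis for Restriction-Site-Anchored Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for restriction-site-anchored reduced-representation DNA
    sequencing of the CUTseq family: in-silico restriction digestion for
    enzyme selection (inter-site distance distributions, bin-wise site
    homogeneity, exon site density, nearest-site distances), a generative
    simulator of barcoded UMI-tagged reads with ground-truth copy-number
    landscapes, a read-processing pipeline (prefix parsing, mismatch-tolerant
    sample demultiplexing, cut-site anchoring, directional UMI
    deduplication), copy-number profiling by fixed-window binning, median
    normalisation and circular binary segmentation with fixed
    amplification/deletion thresholds, and downstream intratumor
    heterogeneity statistics (gene-state matrices, recurrence ranking,
    complete-linkage clustering, replicate concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Rsamtools,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
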