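Package: tol2sites
Title: Insertion-Site Mapping and Integration-Bias Analysis for Tol2
    Transposition Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of transposon integration products from Tol2 (hAT
    superfamily) transposition assays against a circular target plasmid.
    Parses transposon-target junction sequences, maps target flanks onto
    circular plasmid coordinates, detects the 8-bp target-site duplication
    (TSD) diagnostic of hAT transposition, tests per-feature insertion
    occupancy against a length-proportional multinomial null by Monte
    Carlo simulation, calls insertion hotspots across experiments, and
    characterizes the integration-site consensus motif and AT-content
    bias.  A seeded synthetic-data generator emulates the statistical
    structure of junction libraries so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
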