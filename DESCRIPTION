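Package: besmap
Title: BAC-End-Sequence Comparative Mapping and Microsynteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing BAC-end sequences (BES) against a reference
    genome: read trimming and organelle-contamination screening, a built-in
    seed-and-extend read mapper with a brute-force oracle, paired-end
    orientation/span microsynteny classification, genome expansion and
    contraction statistics for concordant clones, hierarchical repeat-content
    ledgers, and clone-library coverage estimation. Includes a synthetic-data
    generator that simulates a rearranged query genome, BAC clones and end
    reads with full planted truth, calibrated to the sugarcane SS_SBa library
    survey, so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
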