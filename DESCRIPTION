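Package: longamp
Title: Long-Amplicon Microbiota Profiling with Full-Length 16S and rrn Operon Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A mapping-based taxonomic profiling pipeline for noisy long
    amplicon reads of two ribosomal markers: the full-length 16S rRNA gene
    (~1.5 kb) and the 16S-ITS-23S region of the rrn operon (~4.3 kb).
    Implements fixed-end trimming and marker-specific length selection,
    minimizer seed-chain-extend alignment with Smith-Waterman-style AS
    scores, coverage-gap chimera removal, block-length and best-AS species
    assignment, reference-database completeness diagnostics, and mock
    community evaluation. Ships a nanopore-like read simulator with truth
    labels so the whole pipeline can be exercised and validated at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
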