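Package: plantmir
Title: Homology-Based Discovery of Conserved Plant miRNAs from
    Transcriptome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico pipeline for discovering conserved microRNAs in
    plant transcriptome assemblies: mismatch-tolerant homology scans of
    known mature miRNAs against transcripts, extraction of candidate
    precursor windows, hairpin folding with a bundled deterministic
    weighted-pairing dynamic program (pluggable for thermodynamic
    backends), a seven-criterion structural and thermodynamic filter
    including the minimal folding free energy index (MFEI), 5p/3p arm
    assignment, detection of polycistronic miRNA clusters on annotated
    references such as pre-rRNA, complementarity-based target-site
    scoring, and Livak 2^-ddCt relative quantification.  A seeded
    synthetic-data generator produces ground-truthed transcriptomes with
    plantable hairpin precursors and criterion-specific decoys so that
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
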