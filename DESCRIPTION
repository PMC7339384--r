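Package: trfphas
Title: tRNA-Derived Fragment and phasiRNA Discovery, Differential
    Expression and Target Analysis for Two-Library Small RNA Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Calls tRNA-derived fragments (tRFs) from exact small-RNA
    alignments by read-end peak detection, classifies them against the
    tRNA cloverleaf (5e-, D-, A-, V- and 3e-tRF) with a 75 percent
    structural-overlap rule, detects 21-nt phased siRNA (phasiRNA) loci
    through a phased ratio/number/abundance score, normalizes tRF,
    phasiRNA and miRNA counts jointly to reads per million, tests
    differential expression between two libraries with the
    Audic-Claverie exact test, predicts phasiRNA targets with a
    miRanda-style complementarity score and nearest-neighbour duplex
    free energy, and integrates differential phasiRNAs with target-gene
    transcript status. A synthetic-data generator with planted ground
    truth makes every stage testable at desk scale, and packaged
    reference tables from a tomato abscisic-acid response experiment
    support exact reproduction of the published aggregate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
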