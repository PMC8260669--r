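Package: paleoevo
Title: LTR Retrotransposon Dating and Whole-Genome Duplication Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the recent evolutionary history of plant
    genomes from sequence alone: structural detection of intact LTR
    retrotransposons, Jukes-Cantor dating of insertions from the divergence of
    their paired terminal repeats, superfamily and lineage classification,
    collinear (syntenic) block detection by anchor chaining, syntenic-depth
    tests for whole-genome duplication, and Ks/4dTv distributions with kernel
    peak detection for dating duplication events. Includes a synthetic-genome
    simulator with full ground truth (planted element ages, planted Ks,
    planted block layout) so every estimator can be validated against known
    answers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
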