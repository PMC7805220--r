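Package: plvscout
Title: Discovery of Polinton-Like Viruses and Virophages in
    Size-Fractionated Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for discovering Polinton-like
    viruses (PLVs) and virophages in assembled metagenomes. Classifies
    contigs by gene sharing with a virophage bait database, confirms
    candidates through capsid-gene profile searches, calls genome
    completeness from circular read mappings and terminal repeats,
    detects target-site duplications at integration sites, quantifies
    enrichment between viral and microbial size fractions, and groups
    genomes into virus clusters from shared protein clusters. Includes a
    synthetic community generator with planted ground truth so every
    stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
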