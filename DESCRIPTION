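Package: est454
Title: Assembly, Digital Expression, qPCR Concordance and EST-SSR Mining
    for Stage-Ordered 454 Transcriptome Libraries
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis chain for pyrosequencing-era expressed sequence
    tag (EST) libraries sampled along ordered developmental or
    physiological stages, such as flower buds across cold acclimation
    (chill-unit time points) and fruit across ripening stages. Provides
    read quality control (adapter masking, minimum-length filtering), a
    deterministic greedy overlap-consensus assembler with per-library
    read tracking, a self-contained k-mer seeded local-alignment search
    with Karlin-Altschul E-values, digital differential expression from
    cross-library read frequencies with categorical stage-trend
    classification, delta-delta-CT relative quantification of qPCR data
    with reference-gene normalization and predicted-versus-observed trend
    concordance, and EST-SSR microsatellite mining with canonical motif
    classing, primer-candidate filtering and marker-screen summaries. A
    synthetic stage-structured transcriptome and 454-like read generator
    with planted expression trends and planted SSR loci makes every stage
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
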