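Package: lichid
Title: Benchmarking Species-Level Identification in ITS2 Metabarcoding of
    Lichen-Forming Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing how reference
    library coverage drives species-level identification success in fungal
    ITS2 amplicon metabarcoding. Generates family-structured reference
    libraries and multi-site bulk communities with realistic divergence
    structure, processes paired-end amplicons into OTUs (read merging,
    primer trimming, swarm-style single-linkage clustering at aggregation
    distance 1, de novo two-parent chimera removal, abundance filtering),
    assigns OTUs to species hypotheses both by a BLAST-style percent
    identity threshold and by a monophyly criterion on family-level
    phylogenies, and compares identification success between a
    high-coverage regional library and a low-coverage global library with
    ANOVA and Tukey HSD post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
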