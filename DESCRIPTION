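Package: estpipe
Title: Comparative EST Analysis: Unigene Assembly, Orthology and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a classic comparative
    expressed-sequence-tag (EST) workflow for non-model green algae: hybrid
    Sanger/454 read cleaning and two-step greedy clustering into unigenes,
    hexamer-based frameshift-aware coding-region prediction, seeded local
    protein alignment with Karlin-Altschul E-values, taxonomic lineage
    binning, multi-species reciprocal-best-hit ortholog cliques with Venn
    partitioning, novel-gene classification, gene-panel screening, and GO
    level-3 enrichment by Fisher's exact test. A synthetic-data module
    generates four-taxon transcriptomes, hybrid reads and machine-readable
    ground truth so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    yaml,
    generics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
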