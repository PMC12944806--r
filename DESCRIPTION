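Package: phenonet
Title: Ontology-Based Phenotypic Similarity and Disease Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps a frequency-annotated symptom profile onto an
    ontology-annotated disease corpus and ranks every disease by five
    phenotypic similarity measures: Jaccard overlap, Resnik information
    content (average and best-match average), GraphIC, and TF-IDF cosine
    similarity with optional query expansion over the ontology graph.
    Includes readers for OBO ontologies and HPOA disease-phenotype
    annotation tables, normalisation of heterogeneous frequency
    annotations, MONDO identifier unification, weighted Kendall tau
    rank comparison with hyperbolic weights, equal-weight rank
    aggregation, high-level disease-category classification, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
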