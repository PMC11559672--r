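Package: cnanet
Title: Copy-Number Alteration Driven Protein Interaction Network Centrality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline that links DNA copy-number alterations
    (CNA) in paired tumor samples to protein-protein interaction (PPI) network
    topology. Segment-level aCGH calls are thresholded into gains and losses,
    mapped through cytobands to protein-coding gene sets, and used to induce
    evidence-filtered interaction subnetworks. Nodes with strictly above-mean
    degree, betweenness, and eigenvector centrality are classified as
    hubs-bottlenecks-switches (HBS); HBS sets are intersected across samples
    and treatment conditions, and Gene Ontology style over-representation is
    assessed with one-sided hypergeometric tests and Benjamini-Hochberg FDR
    control. A deterministic synthetic-data generator emulates every input
    (genome annotation, paired pre/post-chemotherapy CNA profiles, a
    multi-channel interaction table, and an ontology with annotations) with
    planted ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
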