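Package: metabonet
Title: Age-Stratified Metabolic Physiological Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers metabolic physiological networks from participant-level
    biomarker tables and characterizes how their structure changes across age
    groups. Two complementary networks are built per age stratum: an
    undirected network over 15 continuous physiological variables, with
    squared Spearman rank correlations as edge weights gated by a significance
    threshold, and a directed network over 12 threshold-derived binary
    pathological states, with a binomial co-occurrence z-statistic (epsilon)
    as arc weights. The package includes cohort reading, cleaning and age
    stratification; a Gaussian-copula synthetic cohort generator with
    age-group-specific marginals; pathological state assessment (including
    HOMA-IR, CKD-EPI eGFR and the harmonized metabolic syndrome definition);
    centrality (eigencentrality, hub/authority scores, flow betweenness),
    largest-clique and community analysis (Louvain, spinglass); weighted
    clustering and small-world topology summaries; and conditional uniform
    graph (CUG) null-model tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph (>= 1.3),
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
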