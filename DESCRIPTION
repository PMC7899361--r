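Package: dcmnet
Title: Differential Correlation Metabolic Network Analysis for Paired Biofluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how pairwise metabolite correlations differ between two
    paired biofluid compartments (e.g. plasma versus knee joint fluid),
    assesses significance of each differential correlation by permutation,
    builds the signed differential correlation network, and identifies core
    metabolites by topological centrality (degree, betweenness, closeness).
    Includes targeted-metabolomics panel preprocessing (detection-rate filter,
    half-minimum imputation), a synthetic paired-cohort generator with planted
    ground truth for validation, Cytoscape-friendly network export (GraphML,
    SIF), and tidy/broom-style accessors with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
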