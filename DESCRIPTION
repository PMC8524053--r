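Package: bfanet
Title: Bacterial-Fungal Association Networks Across Soil-Root Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative microbial co-occurrence analysis for compartmentalised
    soil-root microbiome studies. Builds intra-domain (bacterial, fungal) and
    inter-domain bacterial-fungal association (BFA) networks from OTU
    abundance tables using random-matrix-theory (RMT) selection of the
    correlation threshold, detects modules by greedy modularity optimisation,
    classifies keystone taxa by within-module (Zi) and among-module (Pi)
    connectivity, compares network topology between compartments, profiles
    quorum-sensing and cobamide gene panels with TPM normalisation and
    pairwise Fisher/Benjamini-Hochberg enrichment, and relates community
    dissimilarity to environmental distance with Mantel tests. Ships a
    synthetic-data generator with planted module structure so every stage
    has a ground-truth test surface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
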