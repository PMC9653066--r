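Package: netniche
Title: Paired-Design Microbiome Networks, Niche Metrics and Assembly Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for paired-design soil microbiome count
    tables: rarefaction and alpha diversity (Chao1, ACE, Fisher's alpha,
    Faith's PD, Good's coverage), normality-gated group comparisons,
    PERMANOVA on Bray-Curtis and Jaccard distances, random-forest
    differential-taxon screening, Pearson co-occurrence network construction
    with Benjamini-Hochberg control, spectral network robustness (natural
    connectivity) under stochastic node and edge removal, Levins niche
    breadth and Pianka overlap with permutation-based generalist/specialist
    classification, a dispersal-niche continuum permutation test built on
    SIMPER profiles, and a conjugate-Gibbs Bayesian path model linking a
    binary treatment to network degree through niche metrics. Includes a
    synthetic paired-community generator with planted differential taxa,
    correlation blocks and assembly scenarios for power and calibration
    studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    ape,
    randomForest,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    withr,
    pracma,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
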