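Package: legacynet
Title: Co-Occurrence Network Analysis of Soil Drought Legacies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to analyse how the intensity of a past drought restructures
    soil microbial communities, from compositional amplicon (ASV) count tables
    to co-occurrence networks and plant-community resilience indices. Includes
    a synthetic-data generator for drought-gradient mesocosm designs with
    planted sparse conditional-dependence graphs; centred log-ratio (CLR)
    preprocessing with Aitchison distances and Shannon diversity; network
    inference by Meinshausen-Buhlmann neighbourhood selection with StARS
    stability selection; network complexity and stability metrics (fast-greedy
    modularity, transitivity, within:between link ratio, targeted-attack
    robustness); maximum-entropy configuration-model null ensembles with
    z-score tests; and baseline-normalised drought resistance and recovery
    indices of plant productivity.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
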