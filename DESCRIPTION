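Package: chronolex
Title: Diachronic Semantic Spaces and Age-Cohort Representational Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating decade-level semantic spaces from diachronic
    word embeddings to the semantic spaces of age cohorts. Builds
    representational similarity matrices (RSMs) from aligned per-decade word
    vectors and from word-association networks (PPMI weighting plus decaying
    Katz random walks), compares them with upper-triangle Spearman RSA,
    split-half reliability and temporal-distance permutation tests, constructs
    lifespan-weighting hypothesis RSMs (early-weighted, uniform,
    recent-weighted), quantifies each decade's predictive contribution through
    cross-validated linear and proportional-odds ablation models, reproduces a
    changed/unchanged-word stimulus-construction procedure for relatedness
    rating studies, and ships a calibrated synthetic-data generator (drifting
    embeddings, cohort learners, association responses, ordinal ratings) so
    the whole pipeline runs without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
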