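Package: folmet
Title: Untargeted Foliar Metabolomics of Wild Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of untargeted LC-MS feature tables from
    field-sampled plant populations: total-intensity normalization,
    pooled-QC relative-standard-deviation filtering, injection-replicate
    averaging and within-plant paired differencing; spatial predictors
    (Euclidean distances and PCNM eigenvectors) and region assignment;
    Bray-Curtis ordination and variation partitioning with permutation
    tests; a per-feature conditional log-normal (two-part hurdle) mixed
    model with likelihood-ratio tests, false-discovery-rate correction and
    Tukey post hoc contrasts; Spearman co-occurrence networks; and targeted
    screening of known standards by retention-time and mass windows.
    Includes a synthetic-study generator with planted ground truth that
    emulates a multi-population paired-leaf sampling design, so every
    stage of the pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    lme4,
    lmerTest,
    emmeans,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    mclust
Config/testthat/edition: 3
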