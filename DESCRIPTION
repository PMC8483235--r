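Package: endomix
Title: Longitudinal Airway Microbiome Community Types and Inflammatory
    Endotypes in COPD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking airway microbiome community structure to
    neutrophilic and eosinophilic inflammatory endotypes in longitudinal
    COPD cohorts. Provides community typing by Ward clustering on
    Jensen-Shannon distances with k-medoids validation, sputum
    differential-cell endotype classification, within-patient state
    transition tables, PELT changepoint detection on genus trajectories
    with changepoint-event odds ratios, cross-covariance tracking of
    genus abundances against sputum granulocyte percentages with
    permutation nulls, SparCC compositional co-occurrence networks with
    Louvain modules, residualized genus-mediator correlation, LEfSe-style
    differential abundance with dominance-control normalizations, and a
    seeded synthetic cohort generator that emulates the statistical
    structure of multi-visit sputum microbiome studies for end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    vegan,
    lme4,
    lmerTest,
    igraph,
    mclust,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ape,
    biomformat
Config/testthat/edition: 3
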