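Package: strokeNet
Title: EEG Functional Network Biomarkers of Upper-Limb Motor Function in Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates upper-limb Fugl-Meyer Assessment (UL-FMA) scores in
    chronic stroke from task EEG. Implements imaginary coherency (iCOH)
    functional connectivity during a grasp task, proportional thresholding of
    connectivity matrices into binary graphs, global and local graph-theoretic
    characterization (global efficiency, degree centrality, local efficiency,
    nodal clustering), event-related desynchronization (ERD), task-related
    activity contrasts with rank-sum, Spearman and ANCOVA tests, a group
    threshold scan, and quadratic-scope stepwise regression with leave-one-out
    validation and bootstrap feature stability. Ships a synthetic EEG cohort
    generator with plantable phase-lagged coupling, ERD effects and a known
    outcome model, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'connectivity.R'
    'network.R'
    'pipeline.R'
    'preprocess.R'
    'regression.R'
    'stats.R'
    'strokeNet-package.R'
    'synthdata.R'
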