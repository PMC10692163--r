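Package: alscreen
Title: Two-Tier Active-Learning Virtual Screening with Synthetic Scoring Oracles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for structure-based virtual screening of synthon-style
    combinatorial libraries with a two-tier active-learning protocol. Provides
    an enumerable synthetic compound library with calibrated, partially
    learnable docking-score and rescoring oracles; Morgan-style fingerprints,
    Tanimoto diversity selection and lead-like filtering; a fingerprint
    regression surrogate with atom-removal attribution; campaign orchestration
    for screening and rescoring schedules with bootstrap hit-recall
    estimation; early-enrichment metrics (ROC AUC, RIE); pharmacophore feature
    density grids over 3D poses with OpenDX export; and analysis of
    calcein-AM efflux, dose-response (three-parameter logistic IC50) and
    vanadate-sensitive ATPase assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    glmnet,
    minpack.lm,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
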