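Package: poxload
Title: Drug-Loading Prediction for Poly(2-oxazoline)/Poly(2-oxazine) Micelles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixture-specific QSPR modelling of drug-loaded ABA-triblock
    poly(2-oxazoline)/poly(2-oxazine) micelle formulations. Builds
    molar-fraction-weighted physicochemical descriptors, count fingerprints and
    SiRMS simplex descriptors for polymer-drug mixtures, derives loading
    capacity (LC) and loading efficiency (LE) threshold labels, trains
    downsampled repeated cross-validation classifiers with Boruta-style feature
    selection, applies a nearest-neighbour applicability domain, and converts a
    threshold-model ladder into per-formulation solubilized-drug estimates and
    virtual-screening reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ChemmineR,
    ChemmineOB,
    igraph,
    caret,
    ranger,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    kernlab,
    e1071,
    mixOmics,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
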