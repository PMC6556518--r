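Package: photostack
Title: Stacked Regression for Spectroscopy-Based Phenotyping of
    Photosynthetic Capacities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate leaf photosynthetic capacities (maximum
    Rubisco carboxylation rate Vc,max and electron transport rate J1800)
    from hyperspectral leaf reflectance (350-2500 nm) by stacked
    generalization over six regression learners (ANN, SVM, LASSO, random
    forest, Gaussian process, PLS) with a level-2 LASSO meta-model trained
    on out-of-fold predictions. Includes a Farquhar-von Caemmerer-Berry
    (FvCB) photosynthesis model with mesophyll conductance for deriving
    the capacities from A/Ci gas-exchange curves, per-band z-score
    standardization, band-block ablation importance, repeated train/test
    benchmark protocols, and a synthetic-data generator emulating a
    six-genotype tobacco trial for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    data.table,
    glmnet,
    nnet,
    e1071,
    ranger,
    minpack.lm,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
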