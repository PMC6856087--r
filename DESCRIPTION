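Package: gpMET
Title: Multi-Trait, Multi-Environment Genomic Prediction with GBLUP and
    Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genomic prediction for incomplete multi-environment trials.
    Implements marker quality control and the genomic relationship matrix,
    a univariate multi-environment GBLUP with an optional
    genotype-by-environment interaction term (Gibbs sampler and an exact
    fixed-variance mixed-model-equation solver), univariate and
    multi-trait feedforward neural networks on Cholesky-encoded
    relationship features with grid search over units, epochs and layers,
    CV1 random cross-validation and the mean arctangent absolute
    percentage error (MAAPE) metric, plus a synthetic-data generator that
    emulates an incomplete multi-environment wheat trial so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
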