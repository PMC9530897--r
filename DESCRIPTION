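Package: pedgxe
Title: Pedigree-Based Multi-Environment Prediction for Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pedigree-based prediction of genotype performance in
    multi-environment breeding trials. Builds additive (numerator) relationship
    matrices from deep pedigrees by the tabular method, runs a two-stage
    phenotypic analysis (per-trial REML fits with outlier screening and Cullis
    heritabilities, then environment-level BLUEs), fits a family of
    kernel-based mixed models with environment, additive, general/specific
    combining ability and Hadamard-product interaction terms by Bayesian
    multi-kernel Gibbs sampling, and evaluates predictive ability under the
    CV0, CV1 and CV2 cross-validation schemes used for multi-environment
    trials. A synthetic breeding-program generator with known simulation truth
    supports testing and calibration without access to proprietary trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    glmmTMB,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
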