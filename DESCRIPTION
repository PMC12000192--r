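Package: twinpath
Title: Biometric Twin Models for Longitudinal Phenotypes: ACE, Cholesky and
    Independent Pathway Decompositions by Raw-Data Maximum Likelihood
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classical twin-design variance decomposition for same-sex
    monozygotic and dizygotic twin pairs. Provides univariate ACE models with
    scalar and quantitative sex-limitation, longitudinal Cholesky
    decompositions, and independent pathway models (common and trait-specific
    additive genetic, shared environmental and non-shared environmental
    factors), all fitted by full-information (raw-data) maximum likelihood on
    possibly incomplete pair-level phenotype tables. Includes chi-square
    difference tests for nested models, delta-method confidence intervals,
    iterative pruning of small non-significant paths, standardised variance
    decompositions, Cholesky heritability accounting, common/specific
    percentage tables, path-traced A/C/E shares of phenotypic correlations,
    Falconer moment estimators, and a synthetic twin-cohort simulator with
    known generating structure for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
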