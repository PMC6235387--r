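Package: thyrovc
Title: Pedigree Variance-Components Analysis of Thyroid Hormone Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood pedigree variance-components analysis for
    family studies of quantitative thyroid traits (TSH, free T4):
    kinship computation by the recursive tabular method, ACE/AE/CE/E
    heritability models, sex-limitation (genotype-by-sex) models with a
    cross-sex genetic correlation, bivariate polygenic models for
    genetic/environmental/phenotypic correlations (pleiotropy), boundary
    mixture chi-square likelihood-ratio tests, rank-based inverse normal
    transformation, stepwise covariate screening inside the polygenic
    model, and a synthetic family-data generator emulating a
    KNHANES-like household sample.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
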