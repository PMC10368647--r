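Package: pgicorrect
Title: Measurement-Error Corrections for Polygenic Index Regressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting attenuation bias caused by
    measurement error in polygenic indices (PGIs). Includes a forward-in-time
    family-based simulator of unlinked diploid genotypes and phenotypes with
    assortative mating and genetic nurture, vectorized between-family GWAS and
    inverse-variance meta-analysis, PGI construction, genomic-relatedness-based
    restricted maximum likelihood (GREML) estimation of SNP heritability, and
    three estimators of the standardized effect of the true latent PGI:
    ordinary least squares on a meta-analysis PGI, obviously-related
    instrumental variables (ORIV, stacked two-stage least squares with
    clustered standard errors), and the PGI repository correction (PGI-RC).
    A scenario harness replicates the estimators' behaviour across grids of
    discovery and prediction sample sizes, assortative-mating strength, and
    cross-sample genetic correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
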