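Package: bivtwin
Title: Bivariate Variance-Component Twin Models by Full-Information
    Maximum Likelihood
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the classical twin design with two continuous traits
    measured on same-sex monozygotic and dizygotic twin pairs. Simulates
    pair-level data from model-implied covariance structures, estimates
    saturated (unstructured) and biometric ACE/ADE variance-component models
    by full-information maximum likelihood with missing data, runs nested
    likelihood-ratio model-comparison ladders including quantitative and
    scalar sex-limitation models, and reports standardized estimates:
    univariate heritability, bivariate heritability, and genetic and
    environmental correlations with profile-likelihood confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
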