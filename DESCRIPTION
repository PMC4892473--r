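Package: cpgset
Title: Set-Based Association Tests for CpG Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint association tests between a binary phenotype and a set of
    correlated CpG methylation markers (beta-values), as used in
    epigenome-wide association studies. Implements seven set-level tests:
    principal component analysis with a k-df likelihood ratio test (PCA),
    supervised principal components with a permutation null (SPCA), kernel
    PCA with a radial basis kernel (KPCA), the sequence kernel association
    test with Davies-type mixture-of-chi-square p-values (SKAT), a sliced
    inverse regression dimension test (SIR), Hotelling's two-sample T-squared
    test, and a Bonferroni-corrected minimum-p t-test. Also provides a
    Gaussian-copula simulator for beta-distributed methylation values with
    calibrated pairwise Pearson correlations, a library of benchmark
    simulation scenarios, and a Monte Carlo harness that estimates empirical
    type I error and power for any battery of the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    Rcpp,
    optparse
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
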