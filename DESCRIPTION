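Package: gennet
Title: Kernel and Functional Neural Networks for Genetic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two neural-network frameworks for genotype-phenotype modeling.
    The kernel neural network treats the genome-wide effect as a random
    effect whose covariance is a positive combination of hidden kernel
    matrices built from genotype-derived input kernels; variance components
    are estimated by MINQUE (minimum norm quadratic unbiased estimation)
    with optional batch training for large cohorts, and phenotypes are
    predicted by BLUP. The functional neural network represents candidate
    gene genotypes as smooth functions of genomic position on B-spline
    bases and stacks functional layers with roughness-penalized integral
    weights, trained by Adam. Includes readers and writers for PLINK
    bed/bim/fam and ped/map genotypes, GCTA binary GRM kernels, phenotype
    and covariate tables, a synthetic-data simulator, train/test accuracy
    metrics (MSE, correlation, misclassification, AUC), and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, splines, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
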