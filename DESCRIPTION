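Package: mgblup
Title: Metabolomic-Genomic Prediction of Breeding Values by GBLUP and MGBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed model machinery for genomic prediction of breeding
    values in multi-environment plant breeding trials, integrating metabolomic
    features. Implements the genomic relationship matrix (VanRaden method 1)
    after SNP quality control, a metabolomic similarity matrix from
    standardized feature intensities, REML variance component estimation
    (average-information algorithm with EM-type fallback), BLUP solutions for
    genomic BLUP (GBLUP) and the two-step metabolomic-genomic BLUP (MGBLUP),
    heritability decomposition into metabolome-mediated and direct parts,
    leave-one-year-out and leave-one-line-out cross-validation, the LR method
    for ratios of accuracies and dispersion bias, and a synthetic data
    generator for the joint phenotype-metabolome model with known true
    parameters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
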