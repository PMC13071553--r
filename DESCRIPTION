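Package: finemapvc
Title: Variability-Corrected Fine-Mapping from GWAS Summary Statistics and a Reference Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequentist inference on joint ("fine-mapping") regression
    coefficients reconstructed from per-variant marginal association
    coefficients and a linkage-disequilibrium (LD) reference panel. The
    covariance of the reconstructed coefficients is corrected for the extra
    sampling variability introduced by estimating the LD correlation matrix
    from the reference sample, using the asymptotic covariance of the
    vectorized sample correlation matrix. Includes truncated-normal
    post-selection inference for regions chosen by marginal screening
    (selection-adjusted p-values, confidence intervals and a conditional
    maximum-likelihood estimator), Benjamini-Hochberg multiple testing,
    readers for summary-statistics tables and genotype panels (delimited
    matrix or VCF hard calls), and simulation generators for Gaussian and
    pseudo-genotype covariate designs with an FDR/power evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
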