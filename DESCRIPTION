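Package: phenopower
Title: Phenotype Measurement Precision and GWAS Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how phenotype measurement imprecision degrades the
    power of quantitative-trait genome-wide association studies, relative to
    reducing cohort size. Simulates genotype-phenotype cohorts with a known
    additive architecture, degrades the phenotype (Gaussian noise, rounding
    to the nearest 5, sex-specific normal/abnormal binarization), applies
    standard variant and sample quality control including an exact
    Hardy-Weinberg equilibrium test, runs covariate-adjusted association
    scans, detects genome-wide-significant loci by distance-based clustering,
    computes SNP-overlap accuracy and loci sensitivity against a baseline
    scan, and fits the linear models that express a given increase in
    phenotype mean absolute error as an equivalent cohort-size reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
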