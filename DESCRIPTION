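Package: subtypeGWAS
Title: Subphenotype-Stratified Genetic Association for Heterogeneous Case Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Quantitative-trait and subphenotype-stratified case-control
    association analysis for genetically heterogeneous disorders. Builds
    quantitative traits from item-level symptom-severity scores, partitions
    cases into phenotypic subtypes by missing-aware K-means clustering,
    screens SNPs by per-SNP linear regression on the traits, tests the
    retained loci for subtype-dependent allelic association (Pearson
    chi-square, odds ratios, Bonferroni and Benjamini-Hochberg adjustment),
    and reports cross-subtype replication. Includes PLINK PED/MAP text
    genotype input/output, Hardy-Weinberg/missingness/frequency quality
    filters, and a synthetic genotype-phenotype generator with planted
    effects for calibration and parameter-recovery testing.
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
    jsonlite
Config/testthat/edition: 3
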