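Package: mwaskit
Title: Metabolome-Wide Association Studies from Genetic Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end metabolome-wide association study (MWAS) toolkit:
    quality control of metabolite abundance matrices (class-specific missingness
    filters, half-minimum imputation, log10 transform), per-metabolite additive
    genome-wide association with covariate and principal-component control,
    fixed-effect inverse-variance-weighted meta-analysis, genome-wide metabolite
    prediction models (LASSO/elastic net/ridge over an 11 x 11 penalty grid plus
    clumping-and-thresholding polygenic scores, selected by fourfold
    cross-validation), TWAS-style summary-statistic association testing of
    imputed metabolites against downstream phenotypes (allele harmonization,
    conditional z-score imputation, weighted-score statistic, FDR control), and
    two-sample Mendelian randomization validation (Wald ratio, IVW, Egger,
    weighted median). Includes a seeded synthetic-data generator with planted
    genetic architecture so the whole pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
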