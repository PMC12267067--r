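Package: oncosex
Title: Sex-Biased Cancer Incidence, Signature Scoring and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for sex-stratified cancer epidemiology and
    tumour transcriptomics. Computes women/men incidence-ratio curves from
    age-standardized rates, a premenopausal variation (PV) index with a
    three-way bias classification, and polynomial trend fits; scores tumour
    transcriptomes against melanoma cell-state and pathway-activation gene
    signatures and assigns predominant states; runs a weighted running-sum
    permutation GSEA with NES/FDR filtering; stratifies survival cohorts by
    expression thresholds and compares Kaplan-Meier curves by log-rank; and
    provides the cohort statistics used for mouse metastasis experiments
    (chi-square, Fisher, Mann-Whitney, Kruskal-Wallis with Dunn follow-up,
    Benjamini-Hochberg, lesion-size classification, gene-list intersection).
    Seeded synthetic-data generators emulate every input with planted
    effects so the estimators can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
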