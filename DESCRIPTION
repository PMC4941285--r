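Package: PDL1EMT
Title: PD-L1 and Epithelial-Mesenchymal Transition Association Analysis for
    Head and Neck Squamous Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for linking tumor PD-L1 expression to the
    epithelial-mesenchymal transition (EMT) in head and neck squamous cell
    carcinoma. Implements immunohistochemistry H-score computation and the
    binary marker calls for PD-L1 (>= 5 percent membranous staining), EMT
    phenotype (E-cadherin H-score < 200 with vimentin H-score > 30) and p16
    (>= 70 percent diffuse strong staining); a Bayesian compound covariate
    predictor that scores expression samples with the posterior probability
    of a mesenchymal signature, with leave-one-out cross-validation and
    prevalence-based threshold calibration; contingency-table association
    statistics (Fisher exact tests, odds ratios, logistic regression,
    Wilcoxon rank-sum, Benjamini-Hochberg adjustment); Kaplan-Meier,
    log-rank and Cox proportional-hazards survival analysis; and synthetic
    cohort and expression generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    tools,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
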