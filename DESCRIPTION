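Package: trimediate
Title: Triangulated Mediation Analysis Combining Cohort and Mendelian
    Randomization Evidence
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a three-step framework for assessing molecular
    mediators of the effect of adiposity on cancer risk, with renal cell
    carcinoma as the motivating application. Exposure-to-mediator and
    mediator-to-risk effects are estimated in two parallel arms: directly in
    a longitudinal cohort (linear, Cox proportional hazards and conditional
    logistic models) and genetically via two-sample Mendelian randomization
    (inverse-variance weighted, MR-Egger, MR-PRESSO, Steiger filtering and
    multivariable MR with conditional F statistics), including instrument
    selection by LD clumping and summary-statistic harmonization. Mediators
    with directionally concordant evidence in both arms are carried into
    product-method mediation with Sobel and delta-method uncertainty. A
    synthetic-data generator with a known exposure-mediator-outcome
    structure makes every stage testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: StatisticalMethod, Epidemiology, Survival, SNP,
    GenomeWideAssociation
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'utils.R'
    'simulate-genotypes.R'
    'simulate-traits.R'
    'cohort-io.R'
    'cohort.R'
    'config.R'
    'sumstats-io.R'
    'instruments.R'
    'harmonize.R'
    'mr-estimators.R'
    'mr-sensitivity.R'
    'mr-mvmr.R'
    'mediation.R'
    'triangulate.R'
    'report.R'
    'pipeline.R'
    'simulate-gwas.R'
    'simulate-ncc.R'
    'simulate-study.R'
    'trimediate-package.R'
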