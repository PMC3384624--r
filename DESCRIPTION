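Package: metabnet
Title: Metabolome-Wide Association and Partial-Correlation Networks for
    Body Composition Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control, covariate-adjusted association analysis and
    Gaussian graphical modelling for targeted serum metabolomics panels
    measured against a continuous body-composition phenotype such as the
    fat free mass index (FFMI).  Implements plate-replicate coefficient of
    variation filtering, outlier and missingness handling with regression
    imputation, inverse log-normal standardisation, metabolome-wide linear
    models with an effective-number-of-tests threshold, intra-class
    metabolite ratios scored by the p-gain statistic, and full-order
    partial-correlation networks with Fisher-z edge tests.  A synthetic
    cohort generator emulating a Biocrates-style panel in a population
    cohort provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'panel.R'
    'cohort.R'
    'indices.R'
    'simulate.R'
    'qc.R'
    'transform.R'
    'associate.R'
    'ratios.R'
    'ggm.R'
    'network-io.R'
    'report.R'
    'pipeline.R'
    'cli.R'
    'reference-data.R'
    'utils.R'
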