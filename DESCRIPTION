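Package: darscaling
Title: Diversity-Area Relationship Scaling for Microbiome Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how microbial alpha diversity accumulates as samples
    ("areas") from a cohort are pooled. Implements Hill-number diversity,
    randomized sample-accumulation curves, log-linear fitting of the
    power-law (PL) and power-law-with-exponential-cutoff (PLEC)
    diversity-area models averaged over random sample orderings, the derived
    DAR, pairwise-diversity-overlap (PDO), maximal-accrued-diversity (MAD)
    and local-to-global-diversity (LGD) profiles, and randomization tests
    for between-group differences in the scaling parameters. A synthetic
    cohort generator with a core/satellite occupancy model and lognormal
    abundances supports calibration and power analyses without sequence
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    biomformat,
    ggplot2
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'community-table.R'
    'diversity.R'
    'fitting.R'
    'profiles.R'
    'comparison.R'
    'io.R'
    'plots.R'
    'run-design.R'
    'synthetic.R'
    'utils.R'
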