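Package: DeltaZIP
Title: Knockout-Controlled Co-Immunoprecipitation Proteomics with Delta-Z
    Interactor Scoring
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification (co-IP) proteomics
    experiments that use knockout animals as a background control. Protein
    peak-area matrices from SWATH-DIA quantification are log-transformed and
    Z-normalized over the whole detected population; interactors of the bait
    are called from the mean difference of Z-scores between wild-type and
    knockout immunoprecipitates mapped onto a standard-normal tail.
    Total-proteome cohorts are compared by confidence-scored log2 fold
    changes (stratified bootstrap sign-consistency), proteins are classified
    into a knockout-dependent pathological proteome by sign-consistency
    across four genotype contrasts, and target sets are tested for
    annotation overrepresentation by Fisher's exact test with Bonferroni
    correction. A synthetic-data generator with planted ground truth makes
    every stage testable without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression, Software
RoxygenNote: 7.3.3
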