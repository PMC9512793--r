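Package: oncoprev
Title: Epidemiologically Weighted Pan-Cancer Mutation Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates population-level prevalence of mutated cancer genes by
    combining cohort sequencing profiles with cancer-registry incidence
    weights. Implements two-tier filtering of MAF-style somatic mutation
    tables against a cancer-gene census panel, construction of a gene-by-site
    conditional mutation probability matrix, incidence weight vectors with
    coverage (Q) rescaling and ICD-O-3 to ICD-10 re-weighting, weighted
    mutation proportions with Poisson parametric-bootstrap confidence
    intervals, cohort comparison utilities (top-k overlap, TP53 pattern
    classification, variance-gated t tests), variant-caller concordance
    metrics, and a synthetic-cohort simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'compare.R'
    'concordance.R'
    'epidemiology.R'
    'filtering.R'
    'io.R'
    'oncoprev-package.R'
    'prevalence.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
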