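Package: qpcrSEA
Title: miRNA Set Enrichment Analysis for Two-Condition qPCR miRNome Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-condition qPCR miRNome panel
    experiments: quantification-cycle (Cq) calling by the second-derivative
    maximum of a fitted amplification curve, interplate calibration, spike-in
    quality control, reference-gene delta-Cq normalization, differential
    ranking, and a GSEA-style miRNA set enrichment analysis (running-sum
    enrichment score, permutation-based normalized enrichment score, nominal
    p-value and FDR q-value) over six miRNA set categories, followed by
    multi-tool target-prediction consensus and candidate miRNA selection.
    Includes a panel-structured simulator with planted differential miRNAs
    and planted enriched sets so every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: GeneSetEnrichment, miRNA, qPCR, Normalization, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'candidates.R'
    'collections.R'
    'enrichment.R'
    'pipeline.R'
    'preprocess.R'
    'qpcrSEA-package.R'
    'ranking.R'
    'synthetic.R'
    'utils.R'
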