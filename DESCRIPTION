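Package: paedesign
Title: Composite-Index Scoring, Similarity-Field QSAR and Derivative
    Screening for Phthalate Plasticizer Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing environmentally friendlier phthalic acid
    ester (PAE) plasticizers. Normalizes insulation (permittivity), acute
    fish toxicity (LC50) and bioconcentration (logBCF) endpoints by min-max
    indicator scaling, aggregates them into a weighted comprehensive effect
    index, fits molecular similarity-index (CoMSIA-style) field models by
    partial least squares with leave-one-out cross-validation, and
    enumerates and screens diallyl phthalate (DAP) derivatives with
    percent-change and binding-free-energy-delta reporting. Seeded 3D
    conformer embedding, Gasteiger charges and atomic logP contributions
    are delegated to RDKit through the bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with rdkit, on PATH as 'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
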