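Package: targetwise
Title: Structure-Based Drug Target Prediction with Transcriptome Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the possible protein targets of small-molecule drugs
    from chemical structure alone: rule-based metabolite generation, hashed
    linear-fragment fingerprints, Tanimoto similarity search against a
    compound-target knowledge base, first-neighbor expansion over a
    protein-protein interaction network, and common/similar/unique
    partitioning of target sets across drugs. An independent transcriptome
    arm calls differentially expressed genes with a three-filter cascade
    (per-gene class comparison, false discovery rate, Student t-test) plus a
    fold-change cut, and both arms are scored by hypergeometric
    over-representation against gene-set ontologies. A concordance report
    compares the two arms. Includes seeded synthetic-fixture generators with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    fgsea,
    ChemmineOB,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
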