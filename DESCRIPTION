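Package: BooleanImplications
Title: Boolean Implication Networks for Seed-Gene Discovery in Expression Compendia
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers genes linked to a seed gene (for example a hypoxia
    sensor such as VEGFA) in large log2 expression compendia using Boolean
    implications. Each probe is discretized with a one-step least-squares
    (StepMiner) threshold, probe pairs are tested for sparsely populated
    quadrants of their joint low/high contingency table (BooleanNet S and p
    statistics), and pairs are classified into six relationship classes
    (low=>low, low=>high, high=>low, high=>high, equivalent, opposite).
    Candidate partners of a seed probe are ranked by implication strength and
    passed through a multilayer filter cascade: concordance across alternate
    probesets of the seed, conservation of directionality in a second-species
    (mouse) compendium via an ortholog map, and novelty against a user gene
    list. A hypoxia-response-element (5'-RCGTG-3') motif scanner and a
    synthetic-compendium generator with planted ground-truth relationships
    complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    optparse
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
biocViews: GeneExpression, Network, Transcriptomics, MotifDiscovery
RoxygenNote: 7.3.3
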