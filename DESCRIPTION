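Package: topoenrich
Title: Topology-Aware Pathway Enrichment and Contextual Pathway
    Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pathway enrichment analysis that exploits the connectivity
    encoded in canonical pathway definitions instead of treating pathways
    as flat gene sets.  All pathways are merged into a single pooled
    directed gene graph; per-gene direct evidence of differential
    expression (a two-sample t-test p-value) is complemented by indirect
    evidence summarising the differential expression of a gene's pathway
    neighbours, assessed against a permutation null, and the two are
    combined by Fisher's method.  Combined-evidence-significant genes feed
    a hypergeometric over-representation test per pathway with family-wise
    error control.  The pooled graph also supports directional contextual
    association scores between pathway pairs with permutation p-values,
    distinguishing condition-specific crosstalk from static gene overlap.
    Includes KGML and edge-list pathway readers, GMT export, seeded
    synthetic-data generators with planted differential pathways, and a
    false-positive-rate calibration by gene-label shuffling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
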