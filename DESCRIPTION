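Package: phenorich
Title: Phenotype-Disease Knowledge Enrichment from Patient-Level Co-Occurrence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines {phenotype} -> {disease} association rules from patient
    transaction data, filters them by odds-ratio confidence-interval
    significance, and merges the surviving associations into an existing
    phenotype-disease knowledge base. Builds disease-phenotype bipartite
    graphs for the knowledge base, the mined associations, and their union;
    derives weighted disease-disease similarity graphs from Jaccard
    similarity of significant-phenotype profiles; ranks differential
    diagnosis candidates; and evaluates enrichment via the increment of
    explanatory power (IEP) and diagnostic performance via sensitivity and
    specificity against a curated gold standard. Includes a synthetic cohort
    generator with planted association strengths so the whole pipeline is
    testable without access to protected medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
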