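Package: netpharm
Title: Network Pharmacology Pipeline for Drug Repurposing Candidate Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable network-pharmacology workflow for drug
    repurposing studies: Lipinski/TPSA drug-likeness screening of a compound
    roster, two-stage intersection of predicted drug targets with a disease
    target set, pathway over-representation analysis with rich factors,
    hypergeometric p-values and Benjamini-Hochberg FDR, construction and
    degree analysis of a tripartite pathway-target-drug network, a two-stage
    degree/betweenness centrality filter that isolates a hub target from a
    protein-protein interaction network, and docking-score triage against a
    binding-energy activity threshold. A seeded synthetic-data generator
    emulates the statistical structure of web-database query results so
    every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
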