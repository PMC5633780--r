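Package: herbnp
Title: Network Pharmacology of Herb Pairs: ADME Screening, Bipartite
    Networks and Contribution Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A system-pharmacology toolkit for dissecting the joint action of
    two-herb combinations on a disease, built around the Huangqi (Radix
    Astragali) - Huanglian (Rhizoma Coptidis) pair for diabetes mellitus.
    Screens herbal ingredients by oral bioavailability and Tanimoto
    drug-likeness with a literature-rescue path, maps the chemical space of
    ingredient descriptor tables by principal component analysis, constructs
    compound-target, target-pathway and target-organ bipartite networks with
    exact degree bookkeeping and Cytoscape-compatible export, ranks
    ingredients by a literature-weighted network-efficacy contribution index
    with a cumulative top-N rule, and profiles targets by annotation
    composition, organ distribution and hypergeometric enrichment. Includes
    a seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable without web-server downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
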