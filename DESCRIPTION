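Package: hetepath
Title: Metapath-Constrained HeteSim Ranking and Hub Analysis on Biomedical Predication Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Literature-based discovery tooling for drug repurposing on
    UMLS-style predication knowledge graphs (SemMedDB-like
    subject-predicate-object triples). Provides a typed multigraph container
    with delimited-text I/O, type-level metapath enumeration with exact path
    counting and degree-weighted path counts, the HeteSim relevance measure
    (midpoint-split cosine of reachability distributions, with an independent
    walk-enumeration oracle), per-simulation candidate ranking with score
    normalization and unsupervised rank aggregation, a layered hub-analysis
    pipeline with back- and cross-evaluation producing a final repurposed-drug
    candidate table, and a seeded synthetic predication-graph generator with
    planted ground truth for end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
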