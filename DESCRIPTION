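Package: kgql
Title: Federated Knowledge Graph Query Language and Execution Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A graph-oriented biomedical query language and a federated
    execution core. Queries describe a linear path of hierarchically typed
    concepts (a Biolink-style vocabulary); the engine plans the path against
    per-source semantic transition maps, invokes knowledge sources segment by
    segment with forward propagation of answer bindings, and merges the
    returned subgraphs into a single provenance-annotated knowledge graph
    with post-query filters, JSONPath variable extraction, named-graph
    storage, and a tabular answer view. Ships fixture federations for two
    clinical/biomedical worked examples, a seeded random-federation
    generator, and a brute-force answer oracle for equivalence testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
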