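Package: fedkg
Title: Federated Biomedical Knowledge-Graph Query Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Query a virtual, federated biomedical knowledge graph assembled
    at query time from a registry of semantically annotated web APIs. API
    endpoints are described with a small OpenAPI-extension dialect (semantic
    input/output categories, identifier prefixes, predicate, response
    identifier path); together they form a meta-knowledge graph over which
    TRAPI-style multi-hop graph queries are planned, executed as chained
    calls through a pluggable transport, normalized to canonical
    identifiers, assembled into result sub-graphs matching the query
    topology, and scored using path counts, path lengths and Normalized
    Google Distance similarity. Ships a seeded synthetic annotated-API
    network generator and an in-process fixture transport so the whole
    pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
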