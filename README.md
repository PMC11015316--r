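# fedkg: federated biomedical knowledge-graph querying

Biomedical knowledge is scattered across hundreds of independent web APIs
that disagree on identifiers, response shapes and vocabulary. One common
answer is to download everything and build a centralized knowledge graph.
`fedkg` implements the complementary, federated strategy: each API is
described by a small, semantically precise annotation — the semantic
category and identifier prefix of its inputs and outputs, the predicate
relating them, and a path locating identifiers in its JSON response — and
the knowledge graph exists only *virtually*, assembled at query time by
chaining API calls. The package is aimed at data analysts and tool
builders who want multi-hop graph queries ("which chemicals interact with
genes associated with this disease?") over such an API federation, and at
method developers who need a fully offline, deterministic testbed for
federated query engines.

## The machinery

* **Meta-knowledge graph.** Each annotated operation contributes one edge
  *input category* → *predicate* → *output category*. The meta-KG over all
  registered APIs tells the planner which operations can serve which kinds
  of associations.
* **Query graphs.** Questions are TRAPI-style graphs: nodes pinned to
  CURIEs (e.g. `MONDO:0005148`) or open, optionally category-constrained;
  edges optionally predicate-constrained. Category and predicate
  constraints expand through a miniature Biolink-like hierarchy.
* **Planning and execution.** Every query edge is matched against the
  meta-KG (descendant-or-equal matching, both directions); edges execute
  in frontier order from the pinned nodes, outputs of one hop feeding the
  next, with identifier translation through a normalizer table (e.g.
  Ensembl ↔ NCBI gene IDs) and per-operation error isolation.
* **Assembly and scoring.** Retrieved records join into result sub-graphs
  matching the query topology. Each result scores in [0, 1] from three
  components: support `g(n) = 1 − 1/(1 + ln(1 + n))` over the `n`
  supporting records, mean path length `h(L) = 1/L` from the pinned
  nodes, and mean Normalized Google Distance similarity over adjacent
  bound entities, where

  `NGD(x, y) = [max(log f(x), log f(y)) − log f(x, y)] / [log N − min(log f(x), log f(y))]`

  with occurrence counts from a pluggable co-occurrence table.
* **Synthetic federation.** `generate_network()` builds a seeded, fully
  offline bundle — annotated specs, association tables, normalizer,
  co-occurrence counts — plus an in-process fixture transport and an
  independent brute-force `ground_truth()` oracle.

## Worked example

The package ships a three-API toy deployment (a CTD-like and a
Monarch-like disease–gene API, and a MyChem-like gene–chemical API):

```r
library(fedkg)
d <- system.file("extdata", package = "fedkg")
reg <- load_registry(file.path(d, "config.json"))
tr  <- fixture_transport(reg$metakg$operations, reg$config$associations_dir)
out <- run_query(reg, file.path(d, "query_two_hop.json"), tr)
out$plan
#> <fedkg_query_plan> 2 edges
#>   e0: 2 candidate(s)
#>   e1: 1 candidate(s)
for (r in out$results)
  cat(unlist(r$node_bindings), "score:", round(r$score$total, 4),
      "n_paths:", r$score$n_paths, "\n")
#> MONDO:0005148 NCBIGene:7157 CHEBI:15365 score: 0.611 n_paths: 3
#> MONDO:0005148 NCBIGene:1017 CHEBI:45783 score: 0.5397 n_paths: 2
#> MONDO:0005148 NCBIGene:5468 CHEBI:17234 score: 0.3967 n_paths: 2
```

The query pins `n0` to type 2 diabetes (`MONDO:0005148`) and asks for
genes (`n1`) and chemicals (`n2`) two hops out. Both disease–gene APIs are
planned for `e0`; the top result is supported by three records (the
disease–TP53 association is served by both APIs, and TP53–aspirin by the
chemical API), so its support component and its NGD similarity are
highest. `serialize_response(out$response)` renders the TRAPI-like
response envelope deterministically.

The same engine drives a command line
(`Rscript inst/cli/fedkg.R query --config ... --query ... --out ...`,
with `metakg` and `fixture` subcommands; exit codes 0/2/3 for
success / invalid input / unplannable query).

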