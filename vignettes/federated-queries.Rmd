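---
title: "Federated knowledge-graph queries: model, scoring and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated knowledge-graph queries: model, scoring and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedkg)
```

## The model

`fedkg` answers graph-shaped questions against a knowledge graph that is
never materialized. Knowledge stays behind independent web APIs; what the
engine holds is only *metadata about* those APIs. Each annotated
operation declares, beyond its call mechanics (server, path, method, a
request template with an `{inputs}` placeholder, a response identifier
path, a batch limit), its *semantics*: the category and identifier prefix
of the entities it accepts, the category and prefix of the entities it
returns, and the predicate relating them. The collection of annotations
is itself a graph — the meta-knowledge graph — whose nodes are semantic
categories and whose edges are operations.

A query is a small TRAPI-style graph: nodes pinned to CURIEs or open,
optionally constrained to categories; edges optionally constrained to
predicates. Answering proceeds in three phases:

1. **Planning.** Every query edge is matched against the meta-KG.
   Matching is hierarchy-aware: constraints expand downward through the
   category and predicate trees, so an edge constrained to
   `associated_with` also matches operations annotated with its narrower
   descendants. The operation's categories must be descendant-or-equal
   to the node constraints; *ancestor* categories on the operation side
   do not match, because an operation annotated at the root would
   otherwise be called for every edge, an unhelpful fan-out. Operations
   are matched in both orientations: one whose input matches the edge's
   object side is planned in `reverse`, and its records later bind with
   subject and object swapped. Edges are ordered by frontier expansion
   from the pinned nodes, always taking the lowest qedge id among edges
   touching an already-bound node — the ordering must only guarantee that
   each edge has a bound endpoint when it runs, and the ascending-id
   tie-break makes plans deterministic.
2. **Execution.** For each candidate operation, bound input entities are
   converted to the operation's identifier namespace through normalizer
   equivalents, filtered by prefix, rendered into the request template
   and sent through the transport; output identifiers are extracted via
   the annotation's response path, given the annotation's output prefix
   and category, and both endpoints are normalized to canonical CURIEs.
   Outputs of one hop become inputs of the next. Failures are isolated
   per operation: a failing API is logged and skipped, and the remaining
   candidates still contribute.
3. **Integration and scoring.** Per-edge records join into result
   sub-graphs matching the query topology (a relational join over the
   edges, pinned nodes accepting only their pins), results deduplicate
   on node bindings with supporting records merged, and each result is
   scored and ranked.

## Scoring

The composite score combines three factors, each mapped into [0, 1]:

* **Support.** `g(n) = 1 − 1/(1 + ln(1 + n))` over the number `n` of
  distinct supporting records across all edge bindings. Distinct records
  include distinct API provenance: the same association served by two
  APIs counts twice, deliberately, as independent corroboration.
* **Path length.** `h(L) = 1/L`, where `L` is the mean over open query
  nodes of their shortest edge distance to a pinned node. For branched
  topologies there is no unique notion of "a path"; the
  shortest-distance-from-the-nearest-pin reading is an interpretation,
  chosen because it is well defined for every connected shape.
* **Semantic similarity.** The mean, over entity pairs adjacent in the
  result, of `max(0, 1 − NGD/cap)` with `cap = 1` by default. The
  Normalized Google Distance

  $$NGD(x,y) = \frac{\max(\log f(x), \log f(y)) - \log f(x,y)}
                    {\log N - \min(\log f(x), \log f(y))}$$

  takes its counts from a pluggable co-occurrence table rather than live
  web hit counts, for determinism and offline operation. Terms that
  never co-occur are infinitely distant (similarity 0); pairs with a
  term absent from the table are skipped and, with no computable pair,
  the similarity component is 0.

The total is the weighted sum with weights `(1/3, 1/3, 1/3)` by default,
normalized to sum to one and exposed in `score_config()`. These
functional forms are implementation-defined choices: any bounded,
monotone transform of the path count and any anti-monotone transform of
NGD would satisfy the same contracts (total in [0, 1], never decreased
by an extra supporting record, never increased by a larger pairwise
distance); the logarithmic support curve was chosen so that the tenth
corroborating record matters much less than the second. Scores are
comparable within one query only; no cross-query normalization is
attempted.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `max_batch` | annotation | 100 | identifiers per rendered request |
| `w_paths, w_length, w_sim` | `score_config()` | 1/3 each | component weights (normalized) |
| `ngd_cap` | `score_config()` | 1 | NGD at which similarity saturates to 0 |
| `mean_out_degree` | `generation_params()` | 2 | Poisson fan-out per input entity |
| `n_entities_per_category` | `generation_params()` | 20 | entity pool per category |
| `fraction_synonyms` | `generation_params()` | 0.25 | entities with a second-namespace alias |

## Numerical and degenerate-input choices

* NGD uses natural logarithms (the ratio is base-invariant). A
  degenerate table with `log N ≤ min log f` yields `Inf` rather than a
  negative distance. Self-distance uses `f(x,x) = f(x)` when the pair is
  not stored, giving `NGD(x,x) = 0`.
* Identifier-path lookups never fail at runtime: missing keys yield no
  identifiers, and path syntax is validated once at registry load.
* Unknown identifiers pass through normalization unchanged (flagged)
  rather than being dropped — federated sources disagree, and silent
  loss is worse than an unnormalized node.
* Ties everywhere break on stable lexicographic order (qedge ids in
  plans, candidate op ids, bound CURIEs in rankings), and response JSON
  is serialized with recursively sorted keys, so identical inputs
  produce byte-identical outputs.
* Record deduplication is on `(subject, predicate, object, qedge,
  operation)`; duplicate retrievals of one association by one operation
  collapse, while the same association from different operations is
  kept as distinct provenance.

## Execution design notes

Two decisions deserve explanation. First, `render_subquery()` chunks
inputs by `max_batch`, but `execute_edge()` issues one request per input
entity: the response path yields output identifiers only, so a batched
response cannot attribute outputs to the individual input that produced
them, and record subjects must be exact. Batched rendering remains part
of the transport surface for adapters whose responses are keyed by
input. Second, when a bound entity does not carry an operation's input
prefix, the executor first looks for an equivalent identifier in the
right namespace via the normalizer (the Ensembl-versus-NCBI situation)
and only then filters — conversion before filtering retrieves strictly
more than filtering alone, and the conversion is logged.

The transport is a plain function contract (`request → parsed document
or failure signal`), so any HTTP client can be plugged in
programmatically; the package itself ships only the pure, in-process
fixture transport, which is all the test suite and the command line
need. Queries pinned at both ends are allowed and treated as constrained
joins. Cyclic query graphs are accepted by the join semantics, though
only tree-shaped and cyclic *synthetic* instances are exercised by the
tests.

## The synthetic federation, and what it does not emulate

`generate_network()` emulates the structural features the engine
actually depends on: several APIs with heterogeneous response shapes and
request templates, category-typed entity pools with identifier
namespaces, Poisson out-degree association tables, synonym identifiers
wired into the normalizer, co-occurrence counts derived from the
association adjacency (`f(x) = degree + 1`, `f(x,y)` = direct-edge
indicator plus shared neighbors, `N` = 10× the entity count — cheap,
invariant-satisfying, and non-degenerate for NGD), and configurable
failure modes. The defaults (3 categories × 20 entities, 3 APIs, mean
out-degree 2, chain topology so consecutive categories are always
connected and two-hop queries are plannable) keep exhaustive oracle
enumeration instant while leaving nontrivial join structure; the
acceptance checks run 200 randomized planner fixtures, 100 assembly
instances and 20 seeded federations in well under a minute.

What it does *not* emulate: real response schemas beyond what
annotations declare, latency and pagination, rate limits,
multi-inheritance vocabularies, literature-derived co-occurrence
statistics, or adversarially malformed API output. Passing tests
therefore demonstrate the engine's logic — planning, chaining,
translation, assembly, scoring — not robustness against the long tail
of live-API misbehavior.

## Known limitations

* Chained retrieval can only call an operation whose *input* side is
  already bound. An association that exists in a source but is only
  reachable through an unbound entity is invisible to the engine — an
  inherent property of federated retrieval, not of this implementation.
* Reverse-direction execution matches the annotated predicate verbatim;
  no inverse-predicate vocabulary is applied. Annotations should use the
  canonical predicate direction.
* The category hierarchy is single-inheritance; each annotation carries
  exactly one predicate.
* Whole-graph analytics (centrality, embeddings) are out of scope: the
  federated graph is never in memory.
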