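#' Run a federated query end to end
#'
#' The full three-phase pipeline: plan the query against the registry's
#' meta-KG, execute the plan over the transport (chaining retrieved
#' entities between hops and normalizing identifiers), assemble the
#' records into result sub-graphs, score and rank them, and package the
#' response envelope.
#'
#' @param registry A `fedkg_registry` from [load_registry()], or any list
#'   providing `hierarchy`, `metakg`, `normalizer`, `cooccurrence`.
#' @param query A `fedkg_query_graph`, or JSON text / path parsed with
#'   [parse_query_graph()].
#' @param transport Transport function (e.g. [make_fixture_transport()]).
#' @param config A `fedkg_score_config`.
#' @param verbose Log sub-queries and per-operation outcomes.
#' @return List: `response` (a `fedkg_response`), `results` (scored,
#'   ranked), `record_set`, `plan`, `query_graph`.
#' @examples
#' bundle <- generate_network(generation_params(seed = 42))
#' registry <- bundle_registry(bundle)
#' q <- two_hop_query("Disease", "Gene", "ChemicalEntity",
#'                    pin = bundle$entities$curie[1])
#' out <- run_query(registry, q, make_fixture_transport(bundle))
#' length(out$results)
#' @export
run_query <- function(registry, query, transport, config = score_config(),
                      verbose = FALSE) {
  query_graph <- if (inherits(query, "fedkg_query_graph")) query else
    parse_query_graph(query, registry$hierarchy)
  plan <- plan_query(query_graph, registry$metakg, registry$hierarchy)
  record_set <- execute_plan(plan, query_graph, transport, registry$metakg,
                             registry$normalizer, verbose = verbose)
  results <- assemble(query_graph, record_set, registry$normalizer)
  scored <- rank_results(score_results(results, query_graph,
                                       registry$cooccurrence, config))
  list(
    response = build_response(query_graph, record_set$records, scored),
    results = scored,
    record_set = record_set,
    plan = plan,
    query_graph = query_graph
  )
}

#' In-memory registry view of a synthetic bundle
#'
#' Wraps a generated bundle as the registry structure [run_query()]
#' expects, without writing anything to disk.
#'
#' @param bundle A `fedkg_network_bundle`.
#' @return A `fedkg_registry`-shaped list.
#' @export
bundle_registry <- function(bundle) {
  structure(
    list(
      config = NULL,
      hierarchy = bundle$hierarchy,
      specs = bundle$specs,
      metakg = build_meta_kg(bundle$specs),
      normalizer = bundle$normalizer,
      cooccurrence = bundle$cooccurrence
    ),
    class = "fedkg_registry"
  )
}

#' Construct a two-hop query graph
#'
#' Convenience constructor for the canonical "what chemicals relate to
#' genes associated with this disease?"-shaped question: pinned node
#' `n0`, open intermediate `n1`, open terminal `n2`, edges
#' `e0 (n0 -> n1)` and `e1 (n1 -> n2)`.
#'
#' @param cat0,cat1,cat2 Semantic categories for the three nodes (`NULL`
#'   leaves a node unconstrained).
#' @param pin CURIE(s) pinning `n0`.
#' @param predicates0,predicates1 Optional predicate constraints.
#' @return A `fedkg_query_graph`.
#' @export
two_hop_query <- function(cat0, cat1, cat2, pin,
                          predicates0 = NULL, predicates1 = NULL) {
  node <- function(ids = NULL, categories = NULL) {
    out <- list()
    if (!is.null(ids)) out$ids <- as.list(ids)
    if (!is.null(categories)) out$categories <- as.list(categories)
    out
  }
  edge <- function(s, o, preds = NULL) {
    out <- list(subject = s, object = o)
    if (!is.null(preds)) out$predicates <- as.list(preds)
    out
  }
  doc <- list(message = list(query_graph = list(
    nodes = list(n0 = node(pin, cat0), n1 = node(NULL, cat1),
                 n2 = node(NULL, cat2)),
    edges = list(e0 = edge("n0", "n1", predicates0),
                 e1 = edge("n1", "n2", predicates1))
  )))
  parse_query_graph(doc)
}
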