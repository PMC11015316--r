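#' Assemble records into result sub-graphs
#'
#' Joins the per-edge records into result sub-graphs that match the query
#' topology: each result assigns one concrete entity to every query node
#' such that every query edge is supported by at least one record
#' consistent with the assignment (records from reverse-direction
#' retrieval bind with subject/object swapped). Pinned query nodes only
#' accept their pinned (canonicalized) identifiers. Results are
#' deduplicated on node bindings; all supporting records for an
#' assignment are merged into its edge bindings.
#'
#' For a query with no edges (a single pinned node), each pinned
#' identifier is itself a result.
#'
#' @param query_graph A `fedkg_query_graph`.
#' @param record_set A `fedkg_record_set` (or bare record data.frame).
#' @param normalizer Optional `fedkg_normalizer` used to canonicalize
#'   pinned identifiers before matching.
#' @return List of unscored results: each a list with `node_bindings`
#'   (named list qnode_id -> CURIE) and `edge_bindings` (named list
#'   qedge_id -> character vector of record keys).
#' @export
assemble <- function(query_graph, record_set, normalizer = NULL) {
  records <- if (inherits(record_set, "fedkg_record_set")) {
    record_set$records
  } else {
    record_set
  }
  qnode_ids <- names(query_graph$qnodes)
  pins <- lapply(query_graph$qnodes, function(n) {
    if (is.null(n$ids)) NULL else
      vapply(n$ids, function(c) normalize_curie(c, normalizer)$curie,
             character(1), USE.NAMES = FALSE)
  })
  eids <- names(query_graph$qedges)

  if (length(eids) == 0) {
    # single-node query: pins are the results
    nid <- qnode_ids[1]
    return(lapply(pins[[nid]], function(curie) {
      list(node_bindings = stats::setNames(list(curie), nid),
           edge_bindings = stats::setNames(list(), character(0)))
    }))
  }

  # per-edge support pairs in qedge orientation
  support <- list()
  for (eid in eids) {
    recs <- records[records$qedge_id == eid, , drop = FALSE]
    if (nrow(recs) == 0) return(list())
    e <- query_graph$qedges[[eid]]
    sup <- data.frame(
      s = ifelse(recs$direction == "forward", recs$subject, recs$object),
      o = ifelse(recs$direction == "forward", recs$object, recs$subject),
      key = recs$record_key,
      stringsAsFactors = FALSE
    )
    if (!is.null(pins[[e$subject]])) sup <- sup[sup$s %in% pins[[e$subject]], , drop = FALSE]
    if (!is.null(pins[[e$object]])) sup <- sup[sup$o %in% pins[[e$object]], , drop = FALSE]
    if (nrow(sup) == 0) return(list())
    support[[eid]] <- sup
  }

  # relational join over edges, ordered so each edge shares a bound qnode
  partial <- NULL
  for (eid in order_edges(query_graph)) {
    e <- query_graph$qedges[[eid]]
    pairs <- unique(support[[eid]][, c("s", "o"), drop = FALSE])
    names(pairs) <- c(e$subject, e$object)
    partial <- if (is.null(partial)) {
      pairs
    } else {
      merge(partial, pairs, by = intersect(names(partial), names(pairs)))
    }
    if (nrow(partial) == 0) return(list())
  }
  partial <- unique(partial[, qnode_ids, drop = FALSE])
  # deterministic result order before scoring/ranking
  ord <- do.call(order, c(as.list(partial), list(method = "radix")))
  partial <- partial[ord, , drop = FALSE]

  lapply(seq_len(nrow(partial)), function(i) {
    row <- partial[i, , drop = FALSE]
    eb <- lapply(eids, function(eid) {
      e <- query_graph$qedges[[eid]]
      sup <- support[[eid]]
      sup$key[sup$s == row[[e$subject]] & sup$o == row[[e$object]]]
    })
    names(eb) <- eids
    list(
      node_bindings = stats::setNames(as.list(unlist(row, use.names = FALSE)),
                                      qnode_ids),
      edge_bindings = eb
    )
  })
}
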