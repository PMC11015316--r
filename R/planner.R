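#' Find candidate operations for one query edge
#'
#' Consults the meta-KG for every operation able to serve a query edge.
#' An operation is a *forward* candidate when its input category is a
#' descendant-or-equal of some category constraint on the edge's subject
#' node, its output category a descendant-or-equal of some constraint on
#' the object node, and its predicate lies in the hierarchy expansion of
#' the edge's predicate list. A *reverse* candidate satisfies the converse
#' (input matches the object side); its records are later bound to the
#' edge with subject and object swapped. Unconstrained node categories or
#' edge predicates match everything. Ancestor categories on the operation
#' side do not match, which keeps API fan-out narrow.
#'
#' Equivalent by construction to a brute-force scan of every operation in
#' the registry.
#'
#' @param qedge One qedge (list with `subject`, `object`, `predicates`).
#' @param qnodes The query graph's named qnode list.
#' @param metakg A `fedkg_metakg`.
#' @param hierarchy A `fedkg_hierarchy`.
#' @return A `fedkg_edge_plan`: data.frame with columns `op_id` and
#'   `direction` ("forward"/"reverse"), sorted by op_id then direction.
#' @export
match_operations <- function(qedge, qnodes, metakg, hierarchy) {
  subj_cats <- qnodes[[qedge$subject]]$categories
  obj_cats <- qnodes[[qedge$object]]$categories
  subj_exp <- if (is.null(subj_cats)) NULL else
    expand_tokens(hierarchy, subj_cats, "category")
  obj_exp <- if (is.null(obj_cats)) NULL else
    expand_tokens(hierarchy, obj_cats, "category")
  pred_exp <- if (is.null(qedge$predicates)) NULL else
    expand_tokens(hierarchy, qedge$predicates, "predicate")

  in_set <- function(x, set) is.null(set) | x %in% set
  e <- metakg$edges
  ok_pred <- if (is.null(pred_exp)) rep(TRUE, nrow(e)) else e$predicate %in% pred_exp
  fwd <- ok_pred & in_set(e$subject_category, subj_exp) &
    in_set(e$object_category, obj_exp)
  rev <- ok_pred & in_set(e$subject_category, obj_exp) &
    in_set(e$object_category, subj_exp)

  cand <- rbind(
    data.frame(op_id = e$op_id[fwd],
               direction = rep("forward", sum(fwd)),
               stringsAsFactors = FALSE),
    data.frame(op_id = e$op_id[rev],
               direction = rep("reverse", sum(rev)),
               stringsAsFactors = FALSE)
  )
  cand <- cand[order(cand$op_id, cand$direction, method = "radix"), ,
               drop = FALSE]
  rownames(cand) <- NULL
  structure(cand, class = c("fedkg_edge_plan", "data.frame"))
}

#' Order query edges for execution
#'
#' Chained execution requires that when an edge runs, at least one of its
#' endpoints is already bound — pinned, or produced by an earlier edge.
#' Edges are ordered by frontier expansion from the pinned nodes, always
#' taking the lowest qedge_id among edges touching an already-bound node
#' (breadth-first with an ascending-qedge_id tie-break). Deterministic for
#' a given query graph.
#'
#' @param query_graph A `fedkg_query_graph`.
#' @return Character vector of qedge ids in execution order.
#' @export
order_edges <- function(query_graph) {
  remaining <- sort(names(query_graph$qedges), method = "radix")
  bound <- pinned_qnodes(query_graph)
  order <- character(0)
  while (length(remaining) > 0) {
    touchable <- remaining[vapply(remaining, function(eid) {
      e <- query_graph$qedges[[eid]]
      e$subject %in% bound || e$object %in% bound
    }, logical(1))]
    if (length(touchable) == 0) {
      stop_fedkg("unreachable qedge(s): ", paste(remaining, collapse = ", "),
                 class = "fedkg_internal_error")
    }
    nxt <- touchable[1]
    order <- c(order, nxt)
    e <- query_graph$qedges[[nxt]]
    bound <- unique(c(bound, e$subject, e$object))
    remaining <- setdiff(remaining, nxt)
  }
  order
}

#' Plan a query against the meta-knowledge graph
#'
#' Combines [order_edges()] and [match_operations()] into a query-path
#' plan: an execution order over the query edges plus, per edge, the
#' candidate operations and their directions. Edges with zero candidates
#' are reported as structured warnings in the plan; a query where *every*
#' edge has zero candidates is unplannable.
#'
#' @param query_graph A `fedkg_query_graph`.
#' @param metakg A `fedkg_metakg`.
#' @param hierarchy A `fedkg_hierarchy`.
#' @return A `fedkg_query_plan`: list with `edge_order`, `edges` (named
#'   list of edge plans) and `warnings` (character vector).
#' @export
plan_query <- function(query_graph, metakg, hierarchy) {
  edge_order <- order_edges(query_graph)
  edges <- lapply(query_graph$qedges[edge_order], match_operations,
                  qnodes = query_graph$qnodes, metakg = metakg,
                  hierarchy = hierarchy)
  n_cand <- vapply(edges, nrow, integer(1))
  warnings <- character(0)
  if (length(edge_order) > 0 && all(n_cand == 0)) {
    stop_fedkg("unplannable query: no candidate operations for any qedge",
               class = "fedkg_unplannable_error")
  }
  for (eid in names(edges)[n_cand == 0]) {
    warnings <- c(warnings,
                  sprintf("qedge '%s' has no candidate operations", eid))
  }
  structure(list(edge_order = edge_order, edges = edges, warnings = warnings),
            class = "fedkg_query_plan")
}

#' @export
print.fedkg_query_plan <- function(x, ...) {
  cat("<fedkg_query_plan>", length(x$edge_order), "edges\n")
  for (eid in x$edge_order) {
    cat("  ", eid, ": ", nrow(x$edges[[eid]]), " candidate(s)\n", sep = "")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Export a query plan as JSON (debugging aid)
#'
#' @param plan A `fedkg_query_plan`.
#' @return JSON text `{edge_order: [...], edges: {qedge_id: [{op_id, direction}]}}`.
#' @export
plan_to_json <- function(plan) {
  edges <- lapply(plan$edges, function(df) {
    lapply(seq_len(nrow(df)), function(i) {
      list(op_id = df$op_id[i], direction = df$direction[i])
    })
  })
  to_sorted_json(list(edge_order = as.list(plan$edge_order),
                      edges = as_json_obj(edges)))
}
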