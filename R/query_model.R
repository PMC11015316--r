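#' Parse a TRAPI-style query graph
#'
#' The question is expressed as a small graph: nodes are either pinned to
#' concrete identifiers (`ids`) or open, optionally constrained to semantic
#' categories; edges connect node pairs and may be constrained to
#' predicates. Input follows the TRAPI shape
#' `{"message": {"query_graph": {"nodes": {...}, "edges": {...}}}}`; only
#' the `ids`, `categories` and `predicates` constraint keys are honored.
#'
#' Validation is total: any input yields either a valid `fedkg_query_graph`
#' or a classed error, never a partially built object. A valid query graph
#' is weakly connected, has at least one pinned node, has no self-loop
#' edges and no dangling edge endpoints.
#'
#' @param doc JSON text, a file path, or an already-parsed nested list.
#' @param hierarchy Optional `fedkg_hierarchy`; when given, node categories
#'   and edge predicates are checked against it.
#' @return A `fedkg_query_graph`: list with `qnodes` (named list; each has
#'   `ids` and `categories`, possibly `NULL`) and `qedges` (named list;
#'   each has `subject`, `object`, `predicates`).
#' @export
parse_query_graph <- function(doc, hierarchy = NULL) {
  if (is.character(doc)) {
    raw <- if (length(doc) == 1 && !grepl("[{\n]", doc) && file.exists(doc)) {
      paste(readLines(doc, warn = FALSE), collapse = "\n")
    } else {
      paste(doc, collapse = "\n")
    }
    doc <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                    error = function(e) {
                      stop_fedkg("malformed query JSON: ", conditionMessage(e),
                                 class = "fedkg_parse_error")
                    })
  }
  qg <- doc$message$query_graph
  if (is.null(qg)) {
    stop_fedkg("document has no message.query_graph",
               class = "fedkg_validation_error")
  }
  nodes <- qg$nodes
  if (is.null(nodes) || length(nodes) == 0 || is.null(names(nodes))) {
    stop_fedkg("query graph has no nodes", class = "fedkg_validation_error")
  }
  qnodes <- list()
  for (nid in names(nodes)) {
    n <- nodes[[nid]]
    ids <- if (!is.null(n$ids)) as.character(unlist(n$ids)) else NULL
    if (!is.null(ids)) {
      if (length(ids) == 0) {
        stop_fedkg("qnode '", nid, "' has an empty ids list",
                   class = "fedkg_validation_error")
      }
      for (id in ids) parse_curie(id)  # format check
    }
    cats <- if (!is.null(n$categories)) as.character(unlist(n$categories)) else NULL
    if (!is.null(cats) && !is.null(hierarchy)) {
      for (cc in cats) {
        if (!hierarchy_has(hierarchy, cc, "category")) {
          stop_fedkg("qnode '", nid, "': unknown category '", cc, "'",
                     class = "fedkg_validation_error")
        }
      }
    }
    qnodes[[nid]] <- list(ids = ids, categories = cats)
  }

  edges <- qg$edges %||% list()
  qedges <- list()
  for (eid in names(edges)) {
    e <- edges[[eid]]
    if (is.null(e$subject) || is.null(e$object)) {
      stop_fedkg("qedge '", eid, "' missing subject or object",
                 class = "fedkg_validation_error")
    }
    subj <- as.character(e$subject)
    obj <- as.character(e$object)
    for (endp in c(subj, obj)) {
      if (!endp %in% names(qnodes)) {
        stop_fedkg("qedge '", eid, "' references unknown qnode '", endp, "'",
                   class = "fedkg_validation_error")
      }
    }
    if (identical(subj, obj)) {
      stop_fedkg("qedge '", eid, "' is a self-loop (subject == object)",
                 class = "fedkg_validation_error")
    }
    preds <- if (!is.null(e$predicates)) as.character(unlist(e$predicates)) else NULL
    if (!is.null(preds) && !is.null(hierarchy)) {
      for (p in preds) {
        if (!hierarchy_has(hierarchy, p, "predicate")) {
          stop_fedkg("qedge '", eid, "': unknown predicate '", p, "'",
                     class = "fedkg_validation_error")
        }
      }
    }
    qedges[[eid]] <- list(subject = subj, object = obj, predicates = preds)
  }

  graph <- structure(list(qnodes = qnodes, qedges = qedges),
                     class = "fedkg_query_graph")
  if (length(pinned_qnodes(graph)) == 0) {
    stop_fedkg("unanchored query: no qnode is pinned to identifiers",
               class = "fedkg_validation_error")
  }
  if (!is_weakly_connected(graph)) {
    stop_fedkg("disconnected query: the query graph is not weakly connected",
               class = "fedkg_validation_error")
  }
  graph
}

pinned_qnodes <- function(query_graph) {
  names(Filter(function(n) !is.null(n$ids) && length(n$ids) > 0,
               query_graph$qnodes))
}

is_weakly_connected <- function(query_graph) {
  ids <- names(query_graph$qnodes)
  if (length(ids) <= 1) return(TRUE)
  seen <- ids[1]
  repeat {
    grew <- FALSE
    for (e in query_graph$qedges) {
      touch <- c(e$subject, e$object)
      if (any(touch %in% seen) && !all(touch %in% seen)) {
        seen <- unique(c(seen, touch))
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  length(seen) == length(ids)
}

#' @export
print.fedkg_query_graph <- function(x, ...) {
  cat("<fedkg_query_graph>", length(x$qnodes), "qnodes,",
      length(x$qedges), "qedges; pinned:",
      paste(pinned_qnodes(x), collapse = ", "), "\n")
  invisible(x)
}

# Named-list JSON object that serializes to {} when empty.
as_json_obj <- function(x) {
  if (length(x) == 0) structure(list(), names = character(0)) else x
}

query_graph_to_list <- function(query_graph) {
  nodes <- lapply(query_graph$qnodes, function(n) {
    out <- list()
    if (!is.null(n$ids)) out$ids <- as.list(n$ids)
    if (!is.null(n$categories)) out$categories <- as.list(n$categories)
    as_json_obj(out)
  })
  edges <- lapply(query_graph$qedges, function(e) {
    out <- list(subject = e$subject, object = e$object)
    if (!is.null(e$predicates)) out$predicates <- as.list(e$predicates)
    out
  })
  list(nodes = as_json_obj(nodes), edges = as_json_obj(edges))
}

#' Build a response envelope
#'
#' Packages scored results with the knowledge graph they reference and an
#' echo of the query graph, in a TRAPI-like shape. Every node and edge
#' referenced by a result binding must exist in the knowledge graph.
#'
#' @param query_graph The `fedkg_query_graph` that was asked.
#' @param records A record data.frame (see [execute_plan()]); may have
#'   zero rows.
#' @param results List of scored results (see [score_results()]); may be
#'   empty.
#' @return A `fedkg_response` list mirroring the serialized structure.
#' @export
build_response <- function(query_graph, records, results = list()) {
  kg_nodes <- list()
  kg_edges <- list()
  if (nrow(records) > 0) {
    ents <- unique(data.frame(
      curie = c(records$subject, records$object),
      category = c(records$subject_category, records$object_category),
      label = c(records$subject_label, records$object_label),
      stringsAsFactors = FALSE))
    for (i in seq_len(nrow(ents))) {
      kg_nodes[[ents$curie[i]]] <- list(category = ents$category[i],
                                        label = ents$label[i])
    }
    for (i in seq_len(nrow(records))) {
      kg_edges[[records$record_key[i]]] <- list(
        subject = records$subject[i],
        predicate = records$predicate[i],
        object = records$object[i],
        api_name = records$api_name[i],
        op_id = records$op_id[i]
      )
    }
  }
  structure(
    list(query_graph = query_graph, kg_nodes = kg_nodes, kg_edges = kg_edges,
         results = results),
    class = "fedkg_response"
  )
}

#' Serialize a response envelope to JSON
#'
#' Deterministic (recursively sorted keys), so serializing the same
#' envelope twice is byte-identical. Result bindings are checked against
#' the knowledge graph: a binding to a missing node or edge is an
#' internal-consistency error.
#'
#' @param response A `fedkg_response` from [build_response()].
#' @return JSON text.
#' @export
serialize_response <- function(response) {
  for (res in response$results) {
    for (curie in unlist(res$node_bindings, use.names = FALSE)) {
      if (!curie %in% names(response$kg_nodes)) {
        stop_fedkg("result binds missing knowledge-graph node: ", curie,
                   class = "fedkg_internal_error")
      }
    }
    for (k in unlist(res$edge_bindings, use.names = FALSE)) {
      if (!k %in% names(response$kg_edges)) {
        stop_fedkg("result binds missing knowledge-graph edge: ", k,
                   class = "fedkg_internal_error")
      }
    }
  }
  results <- lapply(response$results, function(res) {
    list(
      node_bindings = as_json_obj(lapply(res$node_bindings, function(c)
        list(list(id = c)))),
      edge_bindings = as_json_obj(lapply(res$edge_bindings, function(ks)
        lapply(as.list(ks), function(k) list(id = k)))),
      score = res$score$total,
      score_components = list(
        n_paths = res$score$n_paths,
        mean_path_length = res$score$mean_path_length,
        sim = res$score$sim,
        total = res$score$total
      )
    )
  })
  doc <- list(message = list(
    query_graph = query_graph_to_list(response$query_graph),
    knowledge_graph = list(
      nodes = as_json_obj(response$kg_nodes),
      edges = as_json_obj(response$kg_edges)
    ),
    results = results
  ))
  to_sorted_json(doc)
}

#' Parse a serialized response envelope
#'
#' Inverse of [serialize_response()] up to structural equality; used for
#' round-trip checks and by downstream consumers of saved responses.
#'
#' @param text JSON text or file path.
#' @return Parsed nested list (message envelope).
#' @export
parse_response <- function(text) {
  raw <- if (length(text) == 1 && !grepl("[{\n]", text) && file.exists(text)) {
    paste(readLines(text, warn = FALSE), collapse = "\n")
  } else {
    paste(text, collapse = "\n")
  }
  jsonlite::fromJSON(raw, simplifyVector = FALSE)
}
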