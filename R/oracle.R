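#' Brute-force ground truth for a query against a synthetic bundle
#'
#' Exhaustively enumerates, directly over the bundle's association
#' tables, every assignment of concrete entities to query nodes such that
#' each query edge is supported by at least one association retrievable
#' through a compatible, healthy operation (operations in the bundle's
#' `failure_modes` cannot deliver records and are excluded). The oracle
#' deliberately re-derives category/predicate compatibility and entity
#' enumeration on its own, sharing no code with the planner, executor or
#' assembler, so it can serve as an independent reference for end-to-end
#' tests.
#'
#' @param bundle A `fedkg_network_bundle`.
#' @param query_graph A `fedkg_query_graph` valid against the bundle's
#'   vocabulary.
#' @return data.frame with one column per query node (canonical CURIEs),
#'   one row per expected result, sorted; zero rows when the query is
#'   unsatisfiable.
#' @export
ground_truth <- function(bundle, query_graph) {
  # local descendant closure (kept independent of the hierarchy helpers)
  desc_closure <- function(tree, token) {
    out <- token
    repeat {
      kids <- names(tree)[!is.na(tree) & tree %in% out & !names(tree) %in% out]
      if (length(kids) == 0) break
      out <- c(out, kids)
    }
    out
  }
  cat_tree <- bundle$hierarchy$category_parents
  pred_tree <- bundle$hierarchy$predicate_parents

  # canonical map from the raw cluster list
  canon <- new.env(parent = emptyenv())
  for (cl in bundle$normalizer_clusters) {
    for (c in c(cl$canonical, unlist(cl$equivalents))) {
      assign(c, cl$canonical, envir = canon)
    }
  }
  to_canon <- function(x) {
    vapply(x, function(c) {
      if (exists(c, envir = canon, inherits = FALSE)) {
        get(c, envir = canon, inherits = FALSE)
      } else c
    }, character(1), USE.NAMES = FALSE)
  }

  ops <- unlist(lapply(bundle$specs, function(s) s$operations),
                recursive = FALSE)
  healthy <- Filter(function(op) !op$op_id %in% bundle$params$failure_modes,
                    ops)

  qnode_ids <- names(query_graph$qnodes)
  eids <- names(query_graph$qedges)

  if (length(eids) == 0) {
    pins <- to_canon(query_graph$qnodes[[qnode_ids[1]]]$ids)
    df <- stats::setNames(data.frame(sort(unique(pins)),
                                     stringsAsFactors = FALSE), qnode_ids[1])
    return(df)
  }

  cat_ok <- function(op_cat, qnode) {
    cats <- qnode$categories
    if (is.null(cats)) return(TRUE)
    any(vapply(cats, function(cc) op_cat %in% desc_closure(cat_tree, cc),
               logical(1)))
  }
  pred_ok <- function(op_pred, qedge) {
    preds <- qedge$predicates
    if (is.null(preds)) return(TRUE)
    any(vapply(preds, function(p) op_pred %in% desc_closure(pred_tree, p),
               logical(1)))
  }

  # per-edge supported (subject entity, object entity) pairs
  support <- list()
  for (eid in eids) {
    e <- query_graph$qedges[[eid]]
    sn <- query_graph$qnodes[[e$subject]]
    on <- query_graph$qnodes[[e$object]]
    pairs <- character(0)
    for (op in healthy) {
      tab <- bundle$associations[[op$op_id]]
      if (is.null(tab) || nrow(tab) == 0 || !pred_ok(op$predicate, e)) next
      a <- to_canon(tab$input)
      b <- to_canon(tab$output)
      if (cat_ok(op$input_category, sn) && cat_ok(op$output_category, on)) {
        pairs <- c(pairs, paste(a, b, sep = "\r"))
      }
      if (cat_ok(op$input_category, on) && cat_ok(op$output_category, sn)) {
        pairs <- c(pairs, paste(b, a, sep = "\r"))
      }
    }
    pairs <- unique(pairs)
    # pins restrict both ends
    if (length(pairs) > 0) {
      sp <- strsplit(pairs, "\r", fixed = TRUE)
      s <- vapply(sp, `[[`, character(1), 1)
      o <- vapply(sp, `[[`, character(1), 2)
      keep <- rep(TRUE, length(pairs))
      if (!is.null(sn$ids)) keep <- keep & s %in% to_canon(sn$ids)
      if (!is.null(on$ids)) keep <- keep & o %in% to_canon(on$ids)
      support[[eid]] <- data.frame(s = s[keep], o = o[keep],
                                   stringsAsFactors = FALSE)
    } else {
      support[[eid]] <- data.frame(s = character(0), o = character(0),
                                   stringsAsFactors = FALSE)
    }
    if (nrow(support[[eid]]) == 0) {
      return(stats::setNames(
        as.data.frame(replicate(length(qnode_ids), character(0),
                                simplify = FALSE)), qnode_ids))
    }
  }

  # candidate entities per qnode: pins, or entities seen at that side
  candidates <- lapply(qnode_ids, function(nid) {
    qn <- query_graph$qnodes[[nid]]
    if (!is.null(qn$ids)) return(unique(to_canon(qn$ids)))
    seen <- character(0)
    for (eid in eids) {
      e <- query_graph$qedges[[eid]]
      if (e$subject == nid) seen <- c(seen, support[[eid]]$s)
      if (e$object == nid) seen <- c(seen, support[[eid]]$o)
    }
    unique(seen)
  })
  names(candidates) <- qnode_ids

  grid <- do.call(expand.grid, c(candidates,
                                 list(stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE)))
  keep <- rep(TRUE, nrow(grid))
  for (eid in eids) {
    e <- query_graph$qedges[[eid]]
    sup_keys <- paste(support[[eid]]$s, support[[eid]]$o, sep = "\r")
    keep <- keep & paste(grid[[e$subject]], grid[[e$object]],
                         sep = "\r") %in% sup_keys
  }
  out <- unique(grid[keep, qnode_ids, drop = FALSE])
  ord <- do.call(order, c(as.list(out), list(method = "radix")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
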