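# Shared fixtures and independent oracles. The oracles deliberately use a
# different mechanism than the implementation (upward ancestor walks vs
# downward expansion; exhaustive enumeration vs relational joins) so that
# agreement is evidence, not tautology.

example_dir <- function() system.file("extdata", package = "fedkg")

example_hierarchy <- function() {
  load_hierarchy(file.path(example_dir(), "hierarchy.txt"))
}

example_registry <- function() {
  load_registry(file.path(example_dir(), "config.json"))
}

example_transport <- function(registry, failure_modes = character(0)) {
  fixture_transport(registry$metakg$operations,
                    registry$config$associations_dir,
                    failure_modes = failure_modes)
}

# ---- spec document construction ------------------------------------------

make_spec_doc <- function(title, ops, server = NULL) {
  server <- server %||% paste0("https://", gsub("[^a-z0-9]", "",
                                                tolower(title)), ".example.org")
  paths <- list()
  for (op in ops) {
    p <- paste0("/", op$op_id)
    paths[[p]] <- list(`x-kg-operations` = list(op))
  }
  as.character(jsonlite::toJSON(list(
    info = list(title = title, version = "1.0"),
    servers = list(list(url = server)),
    paths = paths
  ), auto_unbox = TRUE))
}

make_op <- function(op_id, in_cat, out_cat, predicate,
                    in_prefix = "PFXIN", out_prefix = "PFXOUT",
                    template = "q={inputs}", id_path = "hits[].id",
                    method = "GET", max_batch = 100) {
  list(op_id = op_id, input_category = in_cat, input_prefix = in_prefix,
       predicate = predicate, output_category = out_cat,
       output_prefix = out_prefix, method = method,
       request_template = template, response_id_path = id_path,
       max_batch = max_batch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- planner oracle: brute-force scan with upward ancestor walks ----------

ancestor_chain <- function(tree, token) {
  out <- token
  cur <- token
  while (!is.na(tree[[cur]])) {
    cur <- tree[[cur]]
    out <- c(out, cur)
  }
  out
}

scan_oracle <- function(qedge, qnodes, metakg, hierarchy) {
  cat_tree <- hierarchy$category_parents
  pred_tree <- hierarchy$predicate_parents
  cat_ok <- function(op_cat, cats) {
    is.null(cats) || any(cats %in% ancestor_chain(cat_tree, op_cat))
  }
  pred_ok <- function(op_pred, preds) {
    is.null(preds) || any(preds %in% ancestor_chain(pred_tree, op_pred))
  }
  subj <- qnodes[[qedge$subject]]$categories
  obj <- qnodes[[qedge$object]]$categories
  rows <- list()
  for (op in metakg$operations) {
    if (pred_ok(op$predicate, qedge$predicates)) {
      if (cat_ok(op$input_category, subj) && cat_ok(op$output_category, obj)) {
        rows[[length(rows) + 1]] <- c(op$op_id, "forward")
      }
      if (cat_ok(op$input_category, obj) && cat_ok(op$output_category, subj)) {
        rows[[length(rows) + 1]] <- c(op$op_id, "reverse")
      }
    }
  }
  df <- if (length(rows) == 0) {
    data.frame(op_id = character(0), direction = character(0),
               stringsAsFactors = FALSE)
  } else {
    m <- do.call(rbind, rows)
    data.frame(op_id = m[, 1], direction = m[, 2], stringsAsFactors = FALSE)
  }
  df <- df[order(df$op_id, df$direction, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random registry + random qedge over the example vocabulary
random_registry <- function(hierarchy, n_ops = NULL) {
  cats <- names(hierarchy$category_parents)
  preds <- names(hierarchy$predicate_parents)
  n_ops <- n_ops %||% sample(1:8, 1)
  n_specs <- sample(1:3, 1)
  ops <- lapply(seq_len(n_ops), function(i) {
    cc <- sample(cats, 2, replace = TRUE)
    make_op(sprintf("rop%03d", i), cc[1], cc[2], sample(preds, 1))
  })
  assignment <- sample(seq_len(n_specs), n_ops, replace = TRUE)
  specs <- lapply(seq_len(n_specs), function(s) {
    parse_api_spec(make_spec_doc(paste0("RandAPI", s),
                                 ops[assignment == s]), hierarchy)
  })
  build_meta_kg(specs)
}

random_qedge_fixture <- function(hierarchy) {
  cats <- names(hierarchy$category_parents)
  preds <- names(hierarchy$predicate_parents)
  maybe <- function(pool, n_max = 2) {
    if (stats::runif(1) < 0.3) NULL else
      sample(pool, sample(seq_len(n_max), 1))
  }
  qnodes <- list(
    n0 = list(ids = "X:1", categories = maybe(cats)),
    n1 = list(ids = NULL, categories = maybe(cats))
  )
  qedge <- list(subject = "n0", object = "n1", predicates = maybe(preds))
  list(qnodes = qnodes, qedge = qedge)
}

# ---- assembler oracle: exhaustive enumeration -----------------------------

# Candidate entities per qnode are its pins (if pinned) or every entity
# observed at that side of an incident edge; any satisfying assignment
# must draw from these, so enumeration over their product is exhaustive.
oracle_assemble_bindings <- function(query_graph, records) {
  qnode_ids <- names(query_graph$qnodes)
  eids <- names(query_graph$qedges)
  oriented <- lapply(eids, function(eid) {
    recs <- records[records$qedge_id == eid, , drop = FALSE]
    data.frame(
      s = ifelse(recs$direction == "forward", recs$subject, recs$object),
      o = ifelse(recs$direction == "forward", recs$object, recs$subject),
      stringsAsFactors = FALSE)
  })
  names(oriented) <- eids
  candidates <- lapply(qnode_ids, function(nid) {
    qn <- query_graph$qnodes[[nid]]
    if (!is.null(qn$ids)) return(unique(qn$ids))
    seen <- character(0)
    for (eid in eids) {
      e <- query_graph$qedges[[eid]]
      if (e$subject == nid) seen <- c(seen, oriented[[eid]]$s)
      if (e$object == nid) seen <- c(seen, oriented[[eid]]$o)
    }
    unique(seen)
  })
  names(candidates) <- qnode_ids
  if (any(lengths(candidates) == 0)) {
    return(stats::setNames(
      as.data.frame(replicate(length(qnode_ids), character(0),
                              simplify = FALSE)), qnode_ids))
  }
  grid <- do.call(expand.grid, c(candidates,
                                 list(stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE)))
  keep <- rep(TRUE, nrow(grid))
  for (eid in eids) {
    e <- query_graph$qedges[[eid]]
    sup <- paste(oriented[[eid]]$s, oriented[[eid]]$o, sep = "\r")
    keep <- keep & paste(grid[[e$subject]], grid[[e$object]],
                         sep = "\r") %in% sup
  }
  out <- unique(grid[keep, qnode_ids, drop = FALSE])
  sort_binding_df(out)
}

sort_binding_df <- function(df) {
  if (nrow(df) > 0) {
    ord <- do.call(order, c(as.list(df), list(method = "radix")))
    df <- df[ord, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

results_to_bindings <- function(results, qnode_ids) {
  if (length(results) == 0) {
    return(stats::setNames(
      as.data.frame(replicate(length(qnode_ids), character(0),
                              simplify = FALSE)), qnode_ids))
  }
  df <- do.call(rbind, lapply(results, function(r) {
    as.data.frame(r$node_bindings[qnode_ids], stringsAsFactors = FALSE)
  }))
  sort_binding_df(df)
}

# random assembly instance: connected random query shape + random records
make_record_df <- function(qedge_id, s, o, direction, op_id) {
  n <- length(s)
  subject <- ifelse(direction == "forward", s, o)
  object <- ifelse(direction == "forward", o, s)
  df <- data.frame(
    qedge_id = rep(qedge_id, n), subject = subject,
    subject_category = rep("NamedThing", n),
    subject_label = subject, predicate = rep("related_to", n),
    object = object, object_category = rep("NamedThing", n),
    object_label = object, api_name = rep("TestAPI", n),
    op_id = op_id, direction = direction,
    input_entity = subject, stringsAsFactors = FALSE)
  df$record_key <- paste(df$subject, df$predicate, df$object, df$qedge_id,
                         df$op_id, sep = "|")
  df[!duplicated(df$record_key), , drop = FALSE]
}

random_assembly_instance <- function(max_qnodes = 4, max_per_edge = 25) {
  n_nodes <- sample(2:max_qnodes, 1)
  qnode_ids <- paste0("n", seq_len(n_nodes) - 1)
  edges <- list()
  for (k in 2:n_nodes) {
    tgt <- sample(seq_len(k - 1), 1)
    pair <- c(qnode_ids[k], qnode_ids[tgt])
    if (stats::runif(1) < 0.5) pair <- rev(pair)
    edges[[length(edges) + 1]] <- pair
  }
  if (n_nodes >= 3 && stats::runif(1) < 0.3) {
    extra <- sample(qnode_ids, 2)
    edges[[length(edges) + 1]] <- extra  # may close a cycle
  }
  eids <- paste0("e", seq_along(edges) - 1)
  pool <- function(nid) paste0("E:", nid, "_", 1:6)
  pins <- sample(pool(qnode_ids[1]), sample(1:2, 1))
  nodes <- stats::setNames(lapply(qnode_ids, function(nid) {
    if (nid == qnode_ids[1]) list(ids = as.list(pins)) else
      structure(list(), names = character(0))
  }), qnode_ids)
  edge_docs <- stats::setNames(lapply(edges, function(p) {
    list(subject = p[1], object = p[2])
  }), eids)
  qg <- parse_query_graph(list(message = list(query_graph = list(
    nodes = nodes, edges = edge_docs))))
  records <- do.call(rbind, lapply(seq_along(eids), function(i) {
    e <- edges[[i]]
    m <- sample(3:max_per_edge, 1)
    s <- sample(c(pool(e[1]), if (e[1] == qnode_ids[1]) pins), m, replace = TRUE)
    o <- sample(pool(e[2]), m, replace = TRUE)
    direction <- sample(c("forward", "reverse"), m, replace = TRUE)
    make_record_df(eids[i], s, o, direction,
                   sample(c("opA", "opB"), m, replace = TRUE))
  }))
  list(query_graph = qg, records = records)
}

# ---- id-path oracle: independent recursive descent ------------------------

oracle_extract <- function(doc, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  walk <- function(node, i) {
    if (i > length(segs)) return(as.character(unlist(node)))
    seg <- segs[i]
    arr <- endsWith(seg, "[]")
    key <- sub("\\[\\]$", "", seg)
    if (!is.list(node) || is.null(node[[key]])) return(character(0))
    child <- node[[key]]
    if (arr) {
      unlist(lapply(child, walk, i = i + 1))
    } else {
      walk(child, i + 1)
    }
  }
  out <- walk(doc, 1)
  if (is.null(out)) character(0) else out
}
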