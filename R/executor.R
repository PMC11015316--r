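#' Render batched sub-queries for one operation
#'
#' Filters the input CURIEs to those carrying the operation's input
#' prefix, chunks them into at most `max_batch` identifiers per request
#' (`ceiling(n / max_batch)` requests), and substitutes the comma-joined
#' local identifiers for the `{inputs}` placeholder of the operation's
#' request template. Zero eligible inputs yield an empty request list, not
#' an error.
#'
#' @param op A `fedkg_operation` annotation.
#' @param input_curies Character vector of input CURIEs.
#' @param max_batch Batch size; defaults to the annotation's `max_batch`.
#' @return List of requests, each a list with `op_id`, `server_url`,
#'   `path`, `method`, `payload` (rendered template) and `inputs` (the
#'   CURIEs in the batch).
#' @export
render_subquery <- function(op, input_curies, max_batch = op$max_batch) {
  eligible <- input_curies[curie_prefix(input_curies) == op$input_prefix]
  if (length(eligible) == 0) return(list())
  chunks <- split(eligible, ceiling(seq_along(eligible) / max_batch))
  lapply(unname(chunks), function(chunk) {
    list(
      op_id = op$op_id,
      server_url = op$server_url,
      path = op$path,
      method = op$method,
      payload = sub("{inputs}", paste(curie_local(chunk), collapse = ","),
                    op$request_template, fixed = TRUE),
      inputs = chunk
    )
  })
}

# Failure signal returned by transports for operations that fail softly.
transport_failure <- function(message) {
  structure(list(message = message), class = "fedkg_transport_failure")
}

is_transport_failure <- function(x) inherits(x, "fedkg_transport_failure")

record_columns <- c("qedge_id", "subject", "subject_category", "subject_label",
                    "predicate", "object", "object_category", "object_label",
                    "api_name", "op_id", "direction", "input_entity",
                    "record_key")

empty_records <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(record_columns), character(0), simplify = FALSE),
    record_columns), stringsAsFactors = FALSE)
  df
}

record_key <- function(df) {
  paste(df$subject, df$predicate, df$object, df$qedge_id, df$op_id, sep = "|")
}

# Convert a curie to the operation's input prefix through normalizer
# equivalents; NA when no equivalent carries that prefix.
convert_to_prefix <- function(curie, prefix, normalizer) {
  if (parse_curie(curie)$prefix == prefix) return(curie)
  eq <- normalizer_equivalents(curie, normalizer)
  hit <- eq[curie_prefix(eq) == prefix]
  if (length(hit) > 0) hit[1] else NA_character_
}

#' Execute one query edge of a plan
#'
#' Runs every candidate operation of the edge against the transport:
#' inputs bound at the operation's input side are converted to the
#' operation's identifier prefix through normalizer equivalents, filtered,
#' rendered and sent; output identifiers are extracted via the
#' annotation's response path and assembled into records carrying the
#' annotation's output prefix, categories and API provenance, with both
#' endpoints normalized to canonical CURIEs. Requests are issued one input
#' at a time so every retrieved identifier is attributed to the input
#' entity that produced it.
#'
#' A failing operation (transport failure signal or error) is logged as a
#' warning and skipped; the remaining candidates still contribute (error
#' isolation). Records are deduplicated on
#' (subject, predicate, object, qedge_id, op_id).
#'
#' @param edge_plan A `fedkg_edge_plan` for this qedge.
#' @param qedge_id The qedge id the records bind to.
#' @param bound_inputs List with `subject` and `object` character vectors
#'   of CURIEs currently bound at the edge's endpoints.
#' @param metakg The `fedkg_metakg` holding the operation annotations.
#' @param transport Transport function: request -> parsed response
#'   document or failure signal.
#' @param normalizer A `fedkg_normalizer` or `NULL`.
#' @param verbose Log each rendered sub-query.
#' @return List: `records` (data.frame), `warnings` (character),
#'   `attempts` (data.frame: op_id, direction, status, n_records).
#' @export
execute_edge <- function(edge_plan, qedge_id, bound_inputs, metakg, transport,
                         normalizer = NULL, verbose = FALSE) {
  recs <- list()
  warns <- character(0)
  attempts <- data.frame(op_id = character(0), direction = character(0),
                         status = character(0), n_records = integer(0),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(edge_plan))) {
    op <- metakg$operations[[edge_plan$op_id[i]]]
    direction <- edge_plan$direction[i]
    side <- if (direction == "forward") "subject" else "object"
    raw_inputs <- unique(bound_inputs[[side]])
    status <- "ok"
    n_new <- 0L
    if (length(raw_inputs) == 0) {
      status <- "no_inputs"
    } else {
      converted <- vapply(raw_inputs, convert_to_prefix, character(1),
                          prefix = op$input_prefix, normalizer = normalizer)
      n_conv <- sum(!is.na(converted) & converted != raw_inputs)
      if (n_conv > 0) {
        fedkg_log("info", sprintf(
          "op %s: converted %d input id(s) to prefix %s via equivalents",
          op$op_id, n_conv, op$input_prefix), verbose = verbose)
      }
      eligible <- unique(converted[!is.na(converted)])
      op_records <- list()
      failed <- FALSE
      for (input_curie in eligible) {
        req <- render_subquery(op, input_curie, max_batch = 1)
        if (length(req) == 0) next
        req <- req[[1]]
        fedkg_log("debug", sprintf("op %s %s %s payload=%s", op$op_id,
                                   req$method, req$path, req$payload),
                  verbose = verbose)
        resp <- tryCatch(transport(req), error = function(e) {
          transport_failure(conditionMessage(e))
        })
        if (is_transport_failure(resp)) {
          warns <- c(warns, sprintf("operation '%s' failed: %s",
                                    op$op_id, resp$message))
          failed <- TRUE
          break
        }
        ids <- extract_ids(resp, op$response_id_path)
        if (length(ids) == 0) next
        subj_norm <- normalize_curie(input_curie, normalizer)
        out_curies <- make_curie(op$output_prefix, ids)
        for (oc in out_curies) {
          obj_norm <- normalize_curie(oc, normalizer)
          op_records[[length(op_records) + 1]] <- data.frame(
            qedge_id = qedge_id,
            subject = subj_norm$curie,
            subject_category = op$input_category,
            subject_label = subj_norm$label,
            predicate = op$predicate,
            object = obj_norm$curie,
            object_category = op$output_category,
            object_label = obj_norm$label,
            api_name = op$api_name,
            op_id = op$op_id,
            direction = direction,
            input_entity = subj_norm$curie,
            stringsAsFactors = FALSE
          )
        }
      }
      if (failed) {
        status <- "failed"
      } else {
        n_new <- length(op_records)
        recs <- c(recs, op_records)
      }
    }
    attempts <- rbind(attempts, data.frame(
      op_id = op$op_id, direction = direction, status = status,
      n_records = n_new, stringsAsFactors = FALSE))
  }
  records <- if (length(recs) == 0) empty_records() else {
    df <- do.call(rbind, recs)
    df$record_key <- record_key(df)
    df <- df[!duplicated(df$record_key), , drop = FALSE]
    rownames(df) <- NULL
    df[, record_columns]
  }
  if (nrow(records) > 0 && !"record_key" %in% names(records)) {
    records$record_key <- record_key(records)
  }
  for (w in warns) fedkg_log("warn", w, verbose = TRUE)
  list(records = records, warnings = warns, attempts = attempts)
}

#' Execute a full query plan
#'
#' Runs the plan's edges in order, chaining retrieved entities: the inputs
#' for edge *k* at a query node are the node's pinned identifiers plus the
#' entities produced there by earlier edges. Query nodes that acquire no
#' entities propagate empty inputs, so downstream edges simply yield no
#' records. Per-operation failures are isolated (see [execute_edge()]);
#' the result is always a well-formed record set.
#'
#' @param plan A `fedkg_query_plan`.
#' @param query_graph The `fedkg_query_graph` the plan was built from.
#' @param transport Transport function (see [make_fixture_transport()]).
#' @param metakg The `fedkg_metakg`.
#' @param normalizer A `fedkg_normalizer` or `NULL`.
#' @param verbose Log sub-queries and conversions.
#' @return A `fedkg_record_set`: list with `records` (data.frame over all
#'   edges, deduplicated), `warnings`, `attempts` (per-edge operation
#'   attempt table with qedge_id column).
#' @export
execute_plan <- function(plan, query_graph, transport, metakg,
                         normalizer = NULL, verbose = FALSE) {
  pins <- pinned_qnodes(query_graph)
  bound <- list()
  for (nid in names(query_graph$qnodes)) {
    ids <- query_graph$qnodes[[nid]]$ids
    bound[[nid]] <- if (is.null(ids)) character(0) else
      vapply(ids, function(c) normalize_curie(c, normalizer)$curie,
             character(1), USE.NAMES = FALSE)
  }
  all_records <- list()
  all_warnings <- character(0)
  all_attempts <- list()
  for (eid in plan$edge_order) {
    qedge <- query_graph$qedges[[eid]]
    res <- execute_edge(
      plan$edges[[eid]], eid,
      bound_inputs = list(subject = bound[[qedge$subject]],
                          object = bound[[qedge$object]]),
      metakg = metakg, transport = transport, normalizer = normalizer,
      verbose = verbose)
    all_warnings <- c(all_warnings, res$warnings)
    if (nrow(res$attempts) > 0) {
      res$attempts <- cbind(data.frame(qedge_id = eid,
                                       stringsAsFactors = FALSE),
                            res$attempts)
    }
    all_attempts[[eid]] <- res$attempts
    recs <- res$records
    if (nrow(recs) > 0) {
      all_records[[eid]] <- recs
      # entities produced at each endpoint, in qedge orientation
      s_ent <- ifelse(recs$direction == "forward", recs$subject, recs$object)
      o_ent <- ifelse(recs$direction == "forward", recs$object, recs$subject)
      if (!qedge$subject %in% pins) {
        bound[[qedge$subject]] <- unique(c(bound[[qedge$subject]], s_ent))
      }
      if (!qedge$object %in% pins) {
        bound[[qedge$object]] <- unique(c(bound[[qedge$object]], o_ent))
      }
    }
  }
  records <- if (length(all_records) == 0) empty_records() else {
    df <- do.call(rbind, all_records)
    df <- df[!duplicated(df$record_key), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  attempts <- if (length(all_attempts) == 0) {
    data.frame(qedge_id = character(0), op_id = character(0),
               direction = character(0), status = character(0),
               n_records = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(all_attempts, list(make.row.names = FALSE)))
  }
  structure(list(records = records, warnings = all_warnings,
                 attempts = attempts),
            class = "fedkg_record_set")
}

#' @export
print.fedkg_record_set <- function(x, ...) {
  cat("<fedkg_record_set>", nrow(x$records), "records over",
      length(unique(x$records$qedge_id)), "qedge(s);",
      length(x$warnings), "warning(s)\n")
  invisible(x)
}
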