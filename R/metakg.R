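#' Build the meta-knowledge graph
#'
#' The meta-knowledge graph (meta-KG) abstracts the registry: its nodes are
#' semantic categories and each edge is one annotated API operation
#' connecting an (input category, output category) pair via a predicate.
#' There is exactly one meta-edge per operation, so the edge count equals
#' the total number of operations across the loaded specs.
#'
#' @param specs List of `fedkg_api_spec` objects.
#' @return A `fedkg_metakg` with elements `categories` (character),
#'   `edges` (data.frame: subject_category, predicate, object_category,
#'   op_id, api_name) and `operations` (named list of annotations, indexed
#'   by op_id).
#' @export
build_meta_kg <- function(specs) {
  all_ops <- unlist(lapply(specs, function(s) s$operations), recursive = FALSE)
  if (length(all_ops) == 0) {
    edges <- data.frame(subject_category = character(0),
                        predicate = character(0),
                        object_category = character(0),
                        op_id = character(0), api_name = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(categories = character(0), edges = edges,
                          operations = list()),
                     class = "fedkg_metakg"))
  }
  ids <- vapply(all_ops, `[[`, character(1), "op_id")
  if (anyDuplicated(ids)) {
    stop_fedkg("duplicate op_id across specs: ", ids[duplicated(ids)][1],
               class = "fedkg_validation_error")
  }
  names(all_ops) <- ids
  edges <- data.frame(
    subject_category = vapply(all_ops, `[[`, character(1), "input_category"),
    predicate = vapply(all_ops, `[[`, character(1), "predicate"),
    object_category = vapply(all_ops, `[[`, character(1), "output_category"),
    op_id = ids,
    api_name = vapply(all_ops, `[[`, character(1), "api_name"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      categories = sort(unique(c(edges$subject_category, edges$object_category))),
      edges = edges,
      operations = all_ops
    ),
    class = "fedkg_metakg"
  )
}

#' Summarize a meta-knowledge graph by category pair
#'
#' For every ordered (subject_category, object_category) pair served by at
#' least one operation, counts the number of distinct APIs (`n_apis`) and
#' the number of operations (`n_operations`). The per-pair operation counts
#' sum to the total number of meta-edges.
#'
#' @param metakg A `fedkg_metakg`.
#' @return data.frame with columns subject_category, object_category,
#'   n_apis, n_operations, ordered by subject then object category.
#' @export
meta_kg_summary <- function(metakg) {
  e <- metakg$edges
  if (nrow(e) == 0) {
    return(data.frame(subject_category = character(0),
                      object_category = character(0),
                      n_apis = integer(0), n_operations = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(e$subject_category, e$object_category, sep = "\r")
  split_api <- split(e$api_name, key)
  keys <- sort(names(split_api))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(
    subject_category = vapply(parts, `[[`, character(1), 1),
    object_category = vapply(parts, `[[`, character(1), 2),
    n_apis = vapply(keys, function(k) length(unique(split_api[[k]])), integer(1)),
    n_operations = vapply(keys, function(k) length(split_api[[k]]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.fedkg_metakg <- function(x, ...) {
  cat("<fedkg_metakg>", length(x$categories), "categories,",
      nrow(x$edges), "meta-edges,",
      length(unique(x$edges$api_name)), "APIs\n")
  invisible(x)
}
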