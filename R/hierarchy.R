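#' Load a category/predicate hierarchy
#'
#' Reads a miniature Biolink-like vocabulary from a flat text file. The file
#' holds one `child<TAB>parent` pair per line; a line `name<TAB>-` marks
#' `name` as a root. Two blocks, separated by a line equal to
#' `#predicates`, give the category tree and the predicate tree. Both trees
#' are single-inheritance: every non-root has exactly one parent and cycles
#' are fatal.
#'
#' @param path Path to the hierarchy file (UTF-8 text).
#' @return A `fedkg_hierarchy` object with elements `category_parents` and
#'   `predicate_parents` (named character vectors, `NA` marking roots).
#' @examples
#' h <- load_hierarchy(fedkg_example("hierarchy.txt"))
#' hierarchy_descendants(h, "ChemicalEntity", "category")
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) {
    stop_fedkg("hierarchy file not found: ", path, class = "fedkg_config_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sep <- which(lines == "#predicates")
  if (length(sep) > 1) {
    stop_fedkg("hierarchy file has more than one '#predicates' separator",
               class = "fedkg_parse_error")
  }
  if (length(sep) == 1) {
    cat_lines <- lines[seq_len(sep - 1)]
    pred_lines <- if (sep < length(lines)) lines[(sep + 1):length(lines)] else character()
  } else {
    cat_lines <- lines
    pred_lines <- character()
  }
  h <- structure(
    list(
      category_parents = parse_parent_block(cat_lines, "category"),
      predicate_parents = parse_parent_block(pred_lines, "predicate")
    ),
    class = "fedkg_hierarchy"
  )
  h
}

# One child<TAB>parent block -> named vector child -> parent (NA for roots).
parse_parent_block <- function(lines, what) {
  if (length(lines) == 0) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop_fedkg("malformed ", what, " hierarchy line: '", lines[bad[1]], "'",
               class = "fedkg_parse_error")
  }
  child <- vapply(parts, `[[`, character(1), 1)
  parent <- vapply(parts, `[[`, character(1), 2)
  if (anyDuplicated(child)) {
    stop_fedkg("duplicate ", what, " entry: ",
               child[duplicated(child)][1], class = "fedkg_parse_error")
  }
  parent[parent == "-"] <- NA_character_
  tree <- stats::setNames(parent, child)
  missing_parent <- setdiff(stats::na.omit(parent), child)
  if (length(missing_parent) > 0) {
    stop_fedkg("unknown parent ", what, ": ", missing_parent[1],
               class = "fedkg_parse_error")
  }
  check_acyclic(tree, what)
  tree
}

# Walk each node to a root; revisiting a node on the same walk is a cycle.
check_acyclic <- function(tree, what) {
  for (node in names(tree)) {
    seen <- character(0)
    cur <- node
    while (!is.na(tree[[cur]])) {
      if (cur %in% seen) {
        stop_fedkg("cycle detected in ", what, " hierarchy at: ", cur,
                   class = "fedkg_parse_error")
      }
      seen <- c(seen, cur)
      cur <- tree[[cur]]
      if (cur %in% seen) {
        stop_fedkg("cycle detected in ", what, " hierarchy at: ", cur,
                   class = "fedkg_parse_error")
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.fedkg_hierarchy <- function(x, ...) {
  cat("<fedkg_hierarchy>", length(x$category_parents), "categories,",
      length(x$predicate_parents), "predicates\n")
  invisible(x)
}

hierarchy_block <- function(hierarchy, kind = c("category", "predicate")) {
  kind <- match.arg(kind)
  if (kind == "category") hierarchy$category_parents else hierarchy$predicate_parents
}

#' Test whether a token exists in the hierarchy
#'
#' @param hierarchy A `fedkg_hierarchy`.
#' @param token Token name.
#' @param kind `"category"` or `"predicate"`.
#' @return Logical scalar.
#' @export
hierarchy_has <- function(hierarchy, token, kind = c("category", "predicate")) {
  token %in% names(hierarchy_block(hierarchy, match.arg(kind)))
}

#' Descendants of a token (reflexive)
#'
#' Returns the token together with all of its descendants in the tree, so
#' `hierarchy_descendants(h, x)` always contains `x`.
#'
#' @inheritParams hierarchy_has
#' @return Character vector of tokens.
#' @export
hierarchy_descendants <- function(hierarchy, token,
                                  kind = c("category", "predicate")) {
  kind <- match.arg(kind)
  tree <- hierarchy_block(hierarchy, kind)
  if (!token %in% names(tree)) {
    stop_fedkg("unknown ", kind, ": ", token, class = "fedkg_validation_error")
  }
  out <- token
  frontier <- token
  while (length(frontier) > 0) {
    kids <- names(tree)[!is.na(tree) & tree %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Expand a category or predicate through the hierarchy
#'
#' Hierarchy-aware expansion used by the planner: a token expands to itself
#' plus all descendants, so constraining a query edge to an ancestor matches
#' every more specific annotation. Expansion is reflexive and monotone
#' (descendants expand to subsets of their ancestors' expansions).
#'
#' @inheritParams hierarchy_has
#' @param tokens Character vector of tokens to expand (union of expansions).
#' @return Character vector: the union of each token with its descendants.
#' @export
expand_tokens <- function(hierarchy, tokens, kind = c("category", "predicate")) {
  kind <- match.arg(kind)
  unique(unlist(lapply(tokens, hierarchy_descendants,
                       hierarchy = hierarchy, kind = kind)))
}
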