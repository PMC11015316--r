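#' Parse a response identifier path
#'
#' The annotation dialect locates output identifiers in a JSON response
#' with a deliberately minimal path language: dot-separated object keys,
#' where a `[]` suffix on a segment maps over the array stored under that
#' key (e.g. `"hits[].id"`, `"data.results[].object.id"`). This is not full
#' JSONPath: no filters, indices or wildcards.
#'
#' Paths are parsed once at registry load so a syntax error is a
#' configuration error, never a runtime one.
#'
#' @param path Character scalar path expression.
#' @return A `fedkg_id_path`: a list of segments, each with `key` and
#'   logical `array`.
#' @export
parse_id_path <- function(path) {
  if (!is.character(path) || length(path) != 1 || is.na(path) || !nzchar(path)) {
    stop_fedkg("response_id_path must be a non-empty string",
               class = "fedkg_config_error")
  }
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(segs) == 0 || any(!nzchar(segs))) {
    stop_fedkg("invalid response_id_path: '", path, "'",
               class = "fedkg_config_error")
  }
  parsed <- lapply(segs, function(s) {
    arr <- grepl("\\[\\]$", s)
    key <- sub("\\[\\]$", "", s)
    if (!grepl("^[A-Za-z_][A-Za-z0-9_-]*$", key)) {
      stop_fedkg("invalid response_id_path segment '", s, "' in '", path, "'",
                 class = "fedkg_config_error")
    }
    list(key = key, array = arr)
  })
  structure(parsed, class = "fedkg_id_path", source = path)
}

#' Extract output identifiers from a response document
#'
#' Applies a parsed identifier path to a response document (nested R lists,
#' as returned by [jsonlite::fromJSON] with `simplifyVector = FALSE`).
#' Missing keys yield no results rather than errors; output order and
#' duplicates are preserved.
#'
#' @param doc Parsed response document (nested lists).
#' @param path A `fedkg_id_path` from [parse_id_path()], or a character
#'   scalar which is parsed on the fly.
#' @return Character vector of identifier strings (possibly empty).
#' @examples
#' doc <- list(hits = list(list(id = "7157"), list(id = "1017")))
#' extract_ids(doc, "hits[].id")
#' @export
extract_ids <- function(doc, path) {
  if (is.character(path)) path <- parse_id_path(path)
  vals <- descend_path(doc, path)
  if (length(vals) == 0) return(character(0))
  as.character(unlist(vals, use.names = FALSE))
}

descend_path <- function(node, segments) {
  if (length(segments) == 0) {
    if (is.null(node) || (is.list(node) && length(node) == 0)) return(list())
    return(list(node))
  }
  seg <- segments[[1]]
  rest <- segments[-1]
  if (!is.list(node) || is.null(names(node)) || !seg$key %in% names(node)) {
    return(list())
  }
  child <- node[[seg$key]]
  if (seg$array) {
    if (!is.list(child) || !is.null(names(child))) {
      # declared as an array but the document holds something else
      return(list())
    }
    out <- list()
    for (el in child) out <- c(out, descend_path(el, rest))
    out
  } else {
    descend_path(child, rest)
  }
}
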