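#' Parse a CURIE
#'
#' A CURIE (compact URI) is `prefix:local_id`, e.g. `NCBIGene:7157`. The
#' split is on the first colon; both parts must be non-empty.
#'
#' @param text Character scalar.
#' @return A list with `prefix`, `local_id` and `curie` (the input).
#' @examples
#' parse_curie("NCBIGene:1017")
#' @export
parse_curie <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop_fedkg("curie must be a single string", class = "fedkg_format_error")
  }
  pos <- regexpr(":", text, fixed = TRUE)
  if (pos < 0) {
    stop_fedkg("not a curie (missing ':'): '", text, "'",
               class = "fedkg_format_error")
  }
  prefix <- substr(text, 1, pos - 1)
  local_id <- substr(text, pos + 1, nchar(text))
  if (!nzchar(prefix) || !nzchar(local_id)) {
    stop_fedkg("not a curie (empty part): '", text, "'",
               class = "fedkg_format_error")
  }
  list(prefix = prefix, local_id = local_id, curie = text)
}

curie_prefix <- function(x) {
  vapply(x, function(s) parse_curie(s)$prefix, character(1), USE.NAMES = FALSE)
}

curie_local <- function(x) {
  vapply(x, function(s) parse_curie(s)$local_id, character(1), USE.NAMES = FALSE)
}

make_curie <- function(prefix, local_id) paste0(prefix, ":", local_id)
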