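# Deterministic JSON: recursively sort object keys so serialization of the
# same structure is byte-identical across runs (golden-file stability).

sort_keys <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && length(nm) > 0 && all(nzchar(nm))) {
      x <- x[order(nm, method = "radix")]
    }
    lapply(x, sort_keys)
  } else {
    x
  }
}

to_sorted_json <- function(x, pretty = TRUE) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE,
                                pretty = pretty, null = "null", digits = NA))
}
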