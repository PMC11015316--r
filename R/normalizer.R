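#' Load an identifier-equivalence (normalizer) table
#'
#' A local stand-in for a node-normalization service: maps every known
#' CURIE to its canonical CURIE plus metadata. File format: JSON array of
#' clusters `{canonical, category, label, equivalents: [...]}`. The
#' closure is idempotent: the canonical of a canonical is itself.
#'
#' @param path Path to the normalizer JSON file.
#' @return A `fedkg_normalizer`: environment mapping curie -> list
#'   (canonical, category, label, equivalents).
#' @export
load_normalizer <- function(path) {
  if (!file.exists(path)) {
    stop_fedkg("normalizer file not found: ", path, class = "fedkg_config_error")
  }
  clusters <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  normalizer_from_clusters(clusters)
}

# Build the lookup from an in-memory cluster list (shared by file loader
# and the synthetic-network generator).
normalizer_from_clusters <- function(clusters) {
  tab <- new.env(parent = emptyenv())
  for (cl in clusters) {
    canonical <- as.character(cl$canonical)
    equivalents <- as.character(unlist(cl$equivalents %||% list()))
    entry <- list(
      canonical = canonical,
      category = as.character(cl$category %||% NA_character_),
      label = as.character(cl$label %||% canonical),
      equivalents = unique(c(canonical, equivalents))
    )
    for (curie in entry$equivalents) assign(curie, entry, envir = tab)
  }
  structure(tab, class = "fedkg_normalizer")
}

#' Normalize a CURIE to canonical form
#'
#' Known identifiers map to their cluster's canonical CURIE with label and
#' category metadata; unknown identifiers pass through unchanged, flagged
#' `normalized = FALSE` (federated sources disagree, and dropping them
#' would silently lose associations).
#'
#' @param curie Character scalar CURIE.
#' @param normalizer A `fedkg_normalizer` (or `NULL`: pass-through).
#' @return List: `curie` (canonical), `label`, `category`, `normalized`.
#' @export
normalize_curie <- function(curie, normalizer) {
  if (!is.null(normalizer) && exists(curie, envir = normalizer, inherits = FALSE)) {
    entry <- get(curie, envir = normalizer, inherits = FALSE)
    list(curie = entry$canonical, label = entry$label,
         category = entry$category, normalized = TRUE)
  } else {
    list(curie = curie, label = curie, category = NA_character_,
         normalized = FALSE)
  }
}

# All equivalents of a curie (including itself); used for prefix conversion.
normalizer_equivalents <- function(curie, normalizer) {
  if (!is.null(normalizer) && exists(curie, envir = normalizer, inherits = FALSE)) {
    get(curie, envir = normalizer, inherits = FALSE)$equivalents
  } else {
    curie
  }
}
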