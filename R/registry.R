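#' Load a registry configuration file
#'
#' The instance-specific configuration selects which annotated API specs a
#' deployment queries and where its supporting tables live. JSON object
#' with keys `specs` (array of spec file paths), `hierarchy`, `normalizer`,
#' `cooccurrence`, and optionally `associations` (directory of per-operation
#' association tables used by the fixture transport; defaults to `data`
#' next to the config file). Relative paths are resolved against the
#' config file's directory; all referenced paths must exist.
#'
#' @param path Path to the JSON config file.
#' @return A `fedkg_registry_config` list of resolved paths.
#' @export
load_registry_config <- function(path) {
  if (!file.exists(path)) {
    stop_fedkg("config file not found: ", path, class = "fedkg_config_error")
  }
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_fedkg("cannot parse config: ", conditionMessage(e),
                               class = "fedkg_config_error")
                  })
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    p <- as.character(p)
    if (grepl("^/", p)) p else file.path(base, p)
  }
  for (key in c("specs", "hierarchy", "normalizer", "cooccurrence")) {
    if (is.null(doc[[key]])) {
      stop_fedkg("config missing key: ", key, class = "fedkg_config_error")
    }
  }
  cfg <- structure(
    list(
      spec_paths = vapply(doc$specs, resolve, character(1)),
      hierarchy_path = resolve(doc$hierarchy),
      normalizer_path = resolve(doc$normalizer),
      cooccurrence_path = resolve(doc$cooccurrence),
      associations_dir = resolve(doc$associations %||% "data")
    ),
    class = "fedkg_registry_config"
  )
  for (p in c(cfg$spec_paths, cfg$hierarchy_path, cfg$normalizer_path,
              cfg$cooccurrence_path)) {
    if (!file.exists(p)) {
      stop_fedkg("configured path does not exist: ", p,
                 class = "fedkg_config_error")
    }
  }
  cfg
}

#' Load a full registry from a configuration
#'
#' Convenience loader: reads the hierarchy, parses and validates every
#' configured API spec, builds the meta-KG, and loads the normalizer and
#' co-occurrence tables.
#'
#' @param config A `fedkg_registry_config` or path to a config file.
#' @return A `fedkg_registry` list: `config`, `hierarchy`, `specs`,
#'   `metakg`, `normalizer`, `cooccurrence`.
#' @export
load_registry <- function(config) {
  if (is.character(config)) config <- load_registry_config(config)
  hierarchy <- load_hierarchy(config$hierarchy_path)
  specs <- lapply(config$spec_paths, parse_api_spec, hierarchy = hierarchy)
  structure(
    list(
      config = config,
      hierarchy = hierarchy,
      specs = specs,
      metakg = build_meta_kg(specs),
      normalizer = load_normalizer(config$normalizer_path),
      cooccurrence = load_cooccurrence(config$cooccurrence_path)
    ),
    class = "fedkg_registry"
  )
}
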