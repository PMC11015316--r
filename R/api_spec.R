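#' Parse a semantically annotated API specification
#'
#' Reads one API spec document in the package's OpenAPI-extension dialect.
#' The document (JSON or YAML) carries ordinary OpenAPI metadata
#' (`info.title`, `info.version`, `servers[0].url`) plus, per endpoint
#' under `paths`, an `x-kg-operations` array of semantic annotations. Each
#' annotation names the operation (`op_id`), the semantic category and
#' identifier prefix of its input and output, the predicate relating them,
#' the HTTP `method`, a `request_template` containing the `{inputs}`
#' placeholder exactly once, a `response_id_path` locating output
#' identifiers in the response (see [parse_id_path()]), and an optional
#' `max_batch` (default 100). Unknown OpenAPI keys are tolerated and
#' ignored.
#'
#' Categories and predicates must resolve in `hierarchy`; violations are
#' validation errors naming the field and operation.
#'
#' @param text Character scalar: the raw JSON or YAML document, or a file
#'   path (detected via [file.exists()]).
#' @param hierarchy A `fedkg_hierarchy` used to validate categories and
#'   predicates.
#' @return A `fedkg_api_spec`: list with `api_name`, `title`, `version`,
#'   `server_url` and `operations` (named list of operation annotations).
#' @export
parse_api_spec <- function(text, hierarchy) {
  doc <- read_spec_document(text)
  info <- doc$info
  if (is.null(info$title)) {
    stop_fedkg("api spec missing info.title", class = "fedkg_validation_error")
  }
  server_url <- if (length(doc$servers) >= 1) doc$servers[[1]]$url else ""
  api_name <- as.character(info$title)

  ops <- list()
  for (path_key in names(doc$paths)) {
    endpoint <- doc$paths[[path_key]]
    raw_ops <- endpoint[["x-kg-operations"]]
    if (is.null(raw_ops)) next
    for (raw in raw_ops) {
      op <- validate_operation(raw, api_name, server_url, path_key, hierarchy)
      if (op$op_id %in% names(ops)) {
        stop_fedkg("duplicate op_id within spec '", api_name, "': ", op$op_id,
                   class = "fedkg_validation_error")
      }
      ops[[op$op_id]] <- op
    }
  }
  structure(
    list(
      api_name = api_name,
      title = api_name,
      version = as.character(info$version %||% "0.0.0"),
      server_url = server_url,
      operations = ops
    ),
    class = "fedkg_api_spec"
  )
}

read_spec_document <- function(text) {
  if (length(text) == 1 && !grepl("[\n{]", text) && file.exists(text)) {
    raw <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                 collapse = "\n")
    is_json <- grepl("^\\s*\\{", raw)
  } else {
    raw <- paste(text, collapse = "\n")
    is_json <- grepl("^\\s*\\{", raw)
  }
  doc <- tryCatch(
    if (is_json) jsonlite::fromJSON(raw, simplifyVector = FALSE)
    else yaml::yaml.load(raw),
    error = function(e) {
      stop_fedkg("cannot parse api spec document: ", conditionMessage(e),
                 class = "fedkg_parse_error")
    }
  )
  if (!is.list(doc)) {
    stop_fedkg("api spec document is not an object", class = "fedkg_parse_error")
  }
  doc
}

required_op_fields <- c("op_id", "input_category", "input_prefix", "predicate",
                        "output_category", "output_prefix",
                        "request_template", "response_id_path")

validate_operation <- function(raw, api_name, server_url, path_key, hierarchy) {
  for (f in required_op_fields) {
    if (is.null(raw[[f]]) || !nzchar(as.character(raw[[f]]))) {
      stop_fedkg("operation in '", api_name, "' (", path_key,
                 ") missing required field: ", f,
                 class = "fedkg_validation_error")
    }
  }
  op_id <- as.character(raw$op_id)
  for (f in c("input_category", "output_category")) {
    if (!hierarchy_has(hierarchy, as.character(raw[[f]]), "category")) {
      stop_fedkg("operation '", op_id, "': unknown category '", raw[[f]],
                 "' in field ", f, class = "fedkg_validation_error")
    }
  }
  if (!hierarchy_has(hierarchy, as.character(raw$predicate), "predicate")) {
    stop_fedkg("operation '", op_id, "': unknown predicate '", raw$predicate,
               "'", class = "fedkg_validation_error")
  }
  template <- as.character(raw$request_template)
  n_ph <- lengths(regmatches(template, gregexpr("{inputs}", template, fixed = TRUE)))
  if (n_ph != 1) {
    stop_fedkg("operation '", op_id, "': request_template must contain ",
               "'{inputs}' exactly once", class = "fedkg_validation_error")
  }
  method <- toupper(as.character(raw$method %||% "GET"))
  if (!method %in% c("GET", "POST")) {
    stop_fedkg("operation '", op_id, "': method must be GET or POST",
               class = "fedkg_validation_error")
  }
  max_batch <- as.integer(raw$max_batch %||% 100L)
  if (is.na(max_batch) || max_batch < 1) {
    stop_fedkg("operation '", op_id, "': max_batch must be a positive integer",
               class = "fedkg_validation_error")
  }
  structure(
    list(
      op_id = op_id,
      api_name = api_name,
      server_url = server_url,
      path = path_key,
      method = method,
      input_category = as.character(raw$input_category),
      input_prefix = as.character(raw$input_prefix),
      output_category = as.character(raw$output_category),
      output_prefix = as.character(raw$output_prefix),
      predicate = as.character(raw$predicate),
      request_template = template,
      response_id_path = parse_id_path(as.character(raw$response_id_path)),
      max_batch = max_batch
    ),
    class = "fedkg_operation"
  )
}

#' Serialize an API spec back to its document form
#'
#' Inverse of [parse_api_spec()] for the fields the dialect defines;
#' `parse_api_spec(serialize_api_spec(x), h)` yields a spec equal to `x`.
#'
#' @param spec A `fedkg_api_spec`.
#' @return JSON text (character scalar).
#' @export
serialize_api_spec <- function(spec) {
  paths <- list()
  for (op in spec$operations) {
    entry <- list(
      op_id = op$op_id,
      input_category = op$input_category,
      input_prefix = op$input_prefix,
      predicate = op$predicate,
      output_category = op$output_category,
      output_prefix = op$output_prefix,
      method = op$method,
      request_template = op$request_template,
      response_id_path = attr(op$response_id_path, "source"),
      max_batch = op$max_batch
    )
    if (is.null(paths[[op$path]])) {
      paths[[op$path]] <- list(`x-kg-operations` = list())
    }
    paths[[op$path]][["x-kg-operations"]] <-
      c(paths[[op$path]][["x-kg-operations"]], list(entry))
  }
  doc <- list(
    info = list(title = spec$api_name, version = spec$version),
    servers = list(list(url = spec$server_url)),
    paths = paths
  )
  to_sorted_json(doc)
}

#' @export
print.fedkg_api_spec <- function(x, ...) {
  cat("<fedkg_api_spec>", x$api_name, "v", x$version, "-",
      length(x$operations), "operations\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
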