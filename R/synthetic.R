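# Synthetic annotated-API network: a fully offline, seeded stand-in for a
# production registry of semantically annotated biomedical APIs. One
# bundle holds everything a deployment needs: annotated specs, per-
# operation association tables, a normalizer table, a co-occurrence table
# and the category/predicate vocabulary.

category_pool <- c("Disease", "Gene", "ChemicalEntity", "PhenotypicFeature",
                   "Protein", "Pathway", "CellType", "AnatomicalEntity")

prefix_pool <- list(
  Disease = c("MONDO", "DOID"),
  Gene = c("NCBIGene", "ENSEMBL"),
  ChemicalEntity = c("CHEBI", "DRUGBANK"),
  PhenotypicFeature = c("HP", "SYNHP"),
  Protein = c("UniProtKB", "PR"),
  Pathway = c("REACT", "KEGG"),
  CellType = c("CL", "SYNCL"),
  AnatomicalEntity = c("UBERON", "SYNUB")
)

leaf_predicates <- c("condition_associated_with_gene",
                     "gene_associated_with_condition",
                     "interacts_with", "treats")

id_path_pool <- c("hits[].id", "data.results[].output_id",
                  "associations[].object.id")

template_pool <- c("q={inputs}", "ids={inputs}", "terms={inputs}")

#' Parameters for the synthetic network generator
#'
#' Defaults describe a small but non-trivial federation: 3 semantic
#' categories of 20 entities each, 3 APIs, mean out-degree 2 per input
#' entity (Poisson fan-out), and a quarter of the entities carrying a
#' synonym identifier under a second prefix.
#'
#' @param seed Integer RNG seed; fully determines the bundle.
#' @param n_categories Number of semantic categories (1-8).
#' @param n_apis Number of APIs to spread operations over.
#' @param n_entities_per_category Entities per category.
#' @param mean_out_degree Poisson mean of out-neighbors per input entity;
#'   must not exceed the entity pool.
#' @param fraction_synonyms Fraction of entities (per category) given an
#'   alias under the category's secondary prefix, wired into the
#'   normalizer table.
#' @param ops_per_category Annotated operations per input category.
#' @param topology `"chain"` links category *i* to category *i+1*
#'   (cyclically), guaranteeing multi-hop queries are plannable;
#'   `"random"` samples output categories.
#' @param failure_modes Character vector of op_ids the fixture transport
#'   will answer with a failure signal.
#' @return A `fedkg_generation_params` list.
#' @export
generation_params <- function(seed = 1,
                              n_categories = 3,
                              n_apis = 3,
                              n_entities_per_category = 20,
                              mean_out_degree = 2,
                              fraction_synonyms = 0.25,
                              ops_per_category = 1,
                              topology = c("chain", "random"),
                              failure_modes = character(0)) {
  topology <- match.arg(topology)
  if (n_categories < 1 || n_categories > length(category_pool)) {
    stop_fedkg("n_categories must be between 1 and ", length(category_pool),
               class = "fedkg_param_error")
  }
  if (n_apis < 1 || n_entities_per_category < 1 || ops_per_category < 1) {
    stop_fedkg("n_apis, n_entities_per_category and ops_per_category must be ",
               "positive", class = "fedkg_param_error")
  }
  if (mean_out_degree < 0 || mean_out_degree > n_entities_per_category) {
    stop_fedkg("mean_out_degree must lie in [0, n_entities_per_category] ",
               "(out-degree cannot exceed the entity pool)",
               class = "fedkg_param_error")
  }
  if (fraction_synonyms < 0 || fraction_synonyms > 1) {
    stop_fedkg("fraction_synonyms must lie in [0, 1]",
               class = "fedkg_param_error")
  }
  structure(list(seed = as.integer(seed), n_categories = n_categories,
                 n_apis = n_apis,
                 n_entities_per_category = n_entities_per_category,
                 mean_out_degree = mean_out_degree,
                 fraction_synonyms = fraction_synonyms,
                 ops_per_category = ops_per_category,
                 topology = topology,
                 failure_modes = as.character(failure_modes)),
            class = "fedkg_generation_params")
}

synthetic_hierarchy_text <- function(categories) {
  cat_lines <- c("NamedThing\t-",
                 paste0(categories, "\tNamedThing"))
  if ("ChemicalEntity" %in% categories) {
    cat_lines <- c(cat_lines, "SmallMolecule\tChemicalEntity")
  }
  pred_lines <- c("related_to\t-",
                  "associated_with\trelated_to",
                  "affects\trelated_to",
                  "interacts_with\trelated_to",
                  "condition_associated_with_gene\tassociated_with",
                  "gene_associated_with_condition\tassociated_with",
                  "treats\taffects")
  paste(c(cat_lines, "#predicates", pred_lines), collapse = "\n")
}

#' Generate a synthetic annotated-API network bundle
#'
#' Builds a complete, seeded offline federation: API specs in the
#' package's annotation dialect, per-operation association tables (pairs
#' drawn with Poisson fan-out without replacement), a normalizer table
#' whose clusters include synonym identifiers under secondary prefixes, a
#' co-occurrence table derived from the association adjacency
#' (`f(x) = degree(x) + 1`, `f(x, y)` = shared-edge indicator + number of
#' shared neighbors, `N` = 10 times the entity count), the miniature
#' vocabulary, and a manifest recording the seed and parameters.
#' Regeneration with the same parameters is deterministic.
#'
#' @param params A `fedkg_generation_params`.
#' @return A `fedkg_network_bundle`.
#' @export
generate_network <- function(params = generation_params()) {
  stopifnot(inherits(params, "fedkg_generation_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  categories <- category_pool[seq_len(params$n_categories)]
  hierarchy_text <- synthetic_hierarchy_text(categories)
  hierarchy <- parse_hierarchy_text(hierarchy_text)

  # entities: one block of local ids per category, prefixed by the
  # category's primary identifier namespace
  entities <- do.call(rbind, lapply(seq_along(categories), function(i) {
    cat_name <- categories[i]
    prefixes <- prefix_pool[[cat_name]]
    n <- params$n_entities_per_category
    local <- sprintf("%d%03d", i, seq_len(n))
    n_alias <- floor(params$fraction_synonyms * n)
    data.frame(
      curie = make_curie(prefixes[1], local),
      category = cat_name,
      label = paste0(tolower(cat_name), "_", local),
      alias = c(make_curie(prefixes[2], local)[seq_len(n_alias)],
                rep(NA_character_, n - n_alias)),
      stringsAsFactors = FALSE
    )
  }))

  # operations: ops_per_category per input category, spread over APIs
  api_names <- paste0("SynthAPI", seq_len(params$n_apis))
  op_defs <- list()
  counter <- 0L
  for (r in seq_len(params$ops_per_category)) {
    for (i in seq_along(categories)) {
      counter <- counter + 1L
      out_i <- if (params$topology == "chain") {
        (i %% length(categories)) + 1L
      } else if (length(categories) == 1) {
        1L
      } else {
        sample(setdiff(seq_along(categories), i), 1)
      }
      in_cat <- categories[i]
      out_cat <- categories[out_i]
      op_id <- sprintf("op%02d_%s_%s", counter, tolower(in_cat),
                       tolower(out_cat))
      op_defs[[op_id]] <- list(
        op_id = op_id,
        api_name = api_names[((counter - 1L) %% params$n_apis) + 1L],
        input_category = in_cat,
        input_prefix = prefix_pool[[in_cat]][1],
        output_category = out_cat,
        output_prefix = prefix_pool[[out_cat]][1],
        predicate = leaf_predicates[((counter - 1L) %% length(leaf_predicates)) + 1L],
        method = "GET",
        request_template = template_pool[((counter - 1L) %% length(template_pool)) + 1L],
        response_id_path = id_path_pool[((counter - 1L) %% length(id_path_pool)) + 1L],
        max_batch = 100L
      )
    }
  }

  # association tables: Poisson fan-out without replacement
  associations <- lapply(op_defs, function(od) {
    ins <- entities$curie[entities$category == od$input_category]
    pool <- entities$curie[entities$category == od$output_category]
    rows <- lapply(ins, function(ic) {
      k <- min(stats::rpois(1, params$mean_out_degree), length(pool))
      if (k == 0) return(NULL)
      data.frame(input = ic, output = sample(pool, k),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) {
      data.frame(input = character(0), output = character(0),
                 stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
  })

  # spec documents, one per API
  spec_docs <- list()
  for (api in api_names) {
    ops_here <- Filter(function(od) od$api_name == api, op_defs)
    paths <- list()
    for (od in ops_here) {
      paths[[paste0("/", od$op_id)]] <- list(`x-kg-operations` = list(
        od[c("op_id", "input_category", "input_prefix", "predicate",
             "output_category", "output_prefix", "method",
             "request_template", "response_id_path", "max_batch")]
      ))
    }
    spec_docs[[api]] <- to_sorted_json(list(
      info = list(title = api, version = "1.0"),
      servers = list(list(url = paste0("https://", tolower(api),
                                       ".example.org"))),
      paths = as_json_obj(paths)
    ))
  }

  # normalizer clusters (every entity; synonyms as equivalents)
  clusters <- lapply(seq_len(nrow(entities)), function(i) {
    eq <- if (is.na(entities$alias[i])) list() else list(entities$alias[i])
    list(canonical = entities$curie[i], category = entities$category[i],
         label = entities$label[i], equivalents = eq)
  })

  cooccurrence_doc <- synthesize_cooccurrence(entities, associations)

  manifest <- list(
    generator = "fedkg synthetic_network",
    seed = params$seed,
    params = unclass(params)
  )

  specs <- lapply(spec_docs, parse_api_spec, hierarchy = hierarchy)
  bundle <- structure(
    list(
      params = params,
      manifest = manifest,
      hierarchy_text = hierarchy_text,
      hierarchy = hierarchy,
      spec_docs = spec_docs,
      specs = unname(specs),
      associations = associations,
      normalizer_clusters = clusters,
      normalizer = normalizer_from_clusters(clusters),
      cooccurrence_doc = cooccurrence_doc,
      cooccurrence = cooccurrence_from_doc(cooccurrence_doc),
      entities = entities
    ),
    class = "fedkg_network_bundle"
  )
  bundle
}

# parse the hierarchy dialect from text (file loader wraps this)
parse_hierarchy_text <- function(text) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(text, tf)
  load_hierarchy(tf)
}

# f(x) = degree + 1 over the simple undirected association graph;
# f2(x, y) = [x ~ y] + |N(x) intersect N(y)|; N = 10 * n_entities.
synthesize_cooccurrence <- function(entities, associations) {
  edges <- unique(do.call(rbind, c(list(data.frame(input = character(0),
                                                   output = character(0),
                                                   stringsAsFactors = FALSE)),
                                   unname(associations))))
  nbrs <- list()
  add_nbr <- function(a, b) {
    nbrs[[a]] <<- unique(c(nbrs[[a]], b))
  }
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      add_nbr(edges$input[i], edges$output[i])
      add_nbr(edges$output[i], edges$input[i])
    }
  }
  terms <- stats::setNames(
    lapply(entities$curie, function(c) length(nbrs[[c]]) + 1),
    entities$curie)
  pair_counts <- new.env(parent = emptyenv())
  bump <- function(a, b, v) {
    k <- pair_key(a, b)
    cur <- if (exists(k, envir = pair_counts, inherits = FALSE)) {
      get(k, envir = pair_counts, inherits = FALSE)
    } else 0
    assign(k, cur + v, envir = pair_counts)
  }
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) bump(edges$input[i], edges$output[i], 1)
  }
  for (z in names(nbrs)) {
    nb <- sort(nbrs[[z]], method = "radix")
    if (length(nb) >= 2) {
      for (i in seq_len(length(nb) - 1)) {
        for (j in (i + 1):length(nb)) bump(nb[i], nb[j], 1)
      }
    }
  }
  pair_names <- sort(ls(envir = pair_counts), method = "radix")
  pairs <- lapply(pair_names, function(k) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(ab[1], ab[2], get(k, envir = pair_counts, inherits = FALSE))
  })
  list(N = nrow(entities) * 10, terms = terms, pairs = pairs)
}

#' Write a network bundle to a directory
#'
#' Layout: `specs/<api>.json`, `data/<op_id>.tsv` (two-column
#' input/output CURIEs), `normalizer.json`, `cooccurrence.json`,
#' `hierarchy.txt`, `manifest.json`, and a ready-to-use `config.json`
#' selecting all specs. File contents are deterministic for a given seed.
#'
#' @param bundle A `fedkg_network_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "specs"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  for (api in names(bundle$spec_docs)) {
    writeLines(bundle$spec_docs[[api]], file.path(dir, "specs",
                                                  paste0(api, ".json")))
  }
  for (op_id in names(bundle$associations)) {
    utils::write.table(bundle$associations[[op_id]],
                       file.path(dir, "data", paste0(op_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(to_sorted_json(bundle$normalizer_clusters),
             file.path(dir, "normalizer.json"))
  writeLines(to_sorted_json(bundle$cooccurrence_doc),
             file.path(dir, "cooccurrence.json"))
  writeLines(bundle$hierarchy_text, file.path(dir, "hierarchy.txt"))
  writeLines(to_sorted_json(bundle$manifest), file.path(dir, "manifest.json"))
  writeLines(to_sorted_json(list(
    specs = as.list(file.path("specs", paste0(names(bundle$spec_docs), ".json"))),
    hierarchy = "hierarchy.txt",
    normalizer = "normalizer.json",
    cooccurrence = "cooccurrence.json",
    associations = "data"
  )), file.path(dir, "config.json"))
  invisible(dir)
}

#' @export
print.fedkg_network_bundle <- function(x, ...) {
  cat("<fedkg_network_bundle> seed", x$params$seed, "-",
      length(x$specs), "APIs,", length(x$associations), "operations,",
      nrow(x$entities), "entities,",
      sum(vapply(x$associations, nrow, integer(1))), "associations\n")
  invisible(x)
}

#' Build the in-process fixture transport for a bundle
#'
#' Returns a pure transport function: a request for a known operation
#' (matched on server URL, path and method) is answered from the bundle's
#' association table for that operation, shaped exactly as the
#' operation's `response_id_path` declares; batched requests return the
#' union of per-input outputs in table order. Operations listed in the
#' bundle's `failure_modes` (or in `failure_modes` here) always return a
#' failure signal. A request for an unknown operation raises a transport
#' error, distinguishable from an empty result.
#'
#' @param bundle A `fedkg_network_bundle`.
#' @param failure_modes Extra op_ids to fail, in addition to the bundle's.
#' @return A transport function `request -> response document`.
#' @export
make_fixture_transport <- function(bundle, failure_modes = character(0)) {
  ops <- unlist(lapply(bundle$specs, function(s) s$operations),
                recursive = FALSE)
  names(ops) <- vapply(ops, `[[`, character(1), "op_id")
  fixture_transport(ops, bundle$associations,
                    failure_modes = unique(c(bundle$params$failure_modes,
                                             failure_modes)))
}

#' Build a fixture transport from operations and association tables
#'
#' Lower-level constructor used by [make_fixture_transport()] and by the
#' command-line front end (which reads per-operation TSV tables from the
#' configured associations directory).
#'
#' @param ops Named list of `fedkg_operation` annotations (by op_id).
#' @param associations Named list of data.frames with `input`/`output`
#'   CURIE columns, or a directory containing `<op_id>.tsv` files.
#' @param failure_modes op_ids answered with a failure signal.
#' @return A transport function.
#' @export
fixture_transport <- function(ops, associations, failure_modes = character(0)) {
  if (is.character(associations)) {
    dir <- associations
    associations <- lapply(names(ops), function(op_id) {
      f <- file.path(dir, paste0(op_id, ".tsv"))
      if (file.exists(f)) {
        utils::read.table(f, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
      } else {
        data.frame(input = character(0), output = character(0),
                   stringsAsFactors = FALSE)
      }
    })
    names(associations) <- names(ops)
  }
  route <- stats::setNames(
    names(ops),
    vapply(ops, function(op) paste(op$server_url, op$path, op$method,
                                   sep = "\r"), character(1)))

  function(request) {
    key <- paste(request$server_url, request$path, request$method, sep = "\r")
    if (!key %in% names(route)) {
      stop_fedkg("fixture transport: unknown operation for ", request$method,
                 " ", request$server_url, request$path,
                 class = "fedkg_transport_error")
    }
    op_id <- route[[key]]
    if (op_id %in% failure_modes) {
      return(transport_failure(paste0("operation '", op_id,
                                      "' is configured to fail")))
    }
    op <- ops[[op_id]]
    locals <- invert_template(op$request_template, request$payload)
    tab <- associations[[op_id]] %||%
      data.frame(input = character(0), output = character(0))
    wanted <- make_curie(op$input_prefix, locals)
    outs <- tab$output[tab$input %in% wanted]
    outs <- unique(outs)  # union of per-input outputs, table order
    build_response_doc(op$response_id_path, curie_local(outs))
  }
}

# Recover the comma-joined local ids a request template was rendered with.
invert_template <- function(template, payload) {
  pos <- regexpr("{inputs}", template, fixed = TRUE)
  prefix <- substr(template, 1, pos - 1)
  suffix <- substring(template, pos + nchar("{inputs}"))
  ok <- nchar(payload) >= nchar(prefix) + nchar(suffix) &&
    substr(payload, 1, nchar(prefix)) == prefix &&
    (nchar(suffix) == 0 ||
       substring(payload, nchar(payload) - nchar(suffix) + 1) == suffix)
  if (pos < 0 || !ok) {
    stop_fedkg("fixture transport: payload does not match request template",
               class = "fedkg_transport_error")
  }
  inner <- substr(payload, nchar(prefix) + 1, nchar(payload) - nchar(suffix))
  ids <- strsplit(inner, ",", fixed = TRUE)[[1]]
  ids[nzchar(ids)]
}

# Shape a value vector as the response document a response_id_path implies.
build_response_doc <- function(id_path, values) {
  if (is.character(id_path)) id_path <- parse_id_path(id_path)
  segments <- unclass(id_path)
  arr_idx <- which(vapply(segments, `[[`, logical(1), "array"))
  arr_idx <- if (length(arr_idx) == 0) NA_integer_ else arr_idx[1]
  build_single <- function(segs, v) {
    if (length(segs) == 0) return(v)
    inner <- build_single(segs[-1], v)
    if (segs[[1]]$array) {
      stats::setNames(list(list(inner)), segs[[1]]$key)
    } else {
      stats::setNames(list(inner), segs[[1]]$key)
    }
  }
  if (is.na(arr_idx)) {
    doc <- as.list(values)
    for (seg in rev(segments)) doc <- stats::setNames(list(doc), seg$key)
    return(doc)
  }
  branches <- lapply(values, function(v) {
    build_single(segments[-seq_len(arr_idx)], v)
  })
  doc <- stats::setNames(list(branches), segments[[arr_idx]]$key)
  if (arr_idx > 1) {
    for (seg in rev(segments[seq_len(arr_idx - 1)])) {
      doc <- stats::setNames(list(doc), seg$key)
    }
  }
  doc
}
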