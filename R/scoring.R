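#' Load a term/pair co-occurrence table
#'
#' Counts backing the Normalized Google Distance: `N` is the corpus size,
#' `terms` maps a CURIE to its occurrence count `f(x)`, and `pairs` holds
#' unordered pair co-occurrence counts `f(x, y)`. Invariants checked at
#' load: all counts non-negative, `f(x) <= N`, and
#' `f(x, y) <= min(f(x), f(y))`.
#'
#' File format: JSON
#' `{"N": int, "terms": {curie: count}, "pairs": [[curieA, curieB, count]]}`.
#'
#' @param path Path to the JSON file.
#' @return A `fedkg_cooccurrence` list: `N`, `f` (named numeric), `f2`
#'   (environment keyed by sorted "a|b").
#' @export
load_cooccurrence <- function(path) {
  if (!file.exists(path)) {
    stop_fedkg("cooccurrence file not found: ", path,
               class = "fedkg_config_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cooccurrence_from_doc(doc)
}

# Build and validate the table from an in-memory document.
cooccurrence_from_doc <- function(doc) {
  N <- as.numeric(doc$N %||% 0)
  f <- vapply(doc$terms %||% list(), as.numeric, numeric(1))
  if (any(f < 0) || any(f > N)) {
    stop_fedkg("cooccurrence term counts must satisfy 0 <= f(x) <= N",
               class = "fedkg_validation_error")
  }
  f2 <- new.env(parent = emptyenv())
  for (p in doc$pairs %||% list()) {
    a <- as.character(p[[1]]); b <- as.character(p[[2]])
    cnt <- as.numeric(p[[3]])
    fa <- if (a %in% names(f)) f[[a]] else 0
    fb <- if (b %in% names(f)) f[[b]] else 0
    if (cnt < 0 || cnt > min(fa, fb)) {
      stop_fedkg("cooccurrence pair count violates f(x,y) <= min(f(x), f(y)) ",
                 "for (", a, ", ", b, ")", class = "fedkg_validation_error")
    }
    assign(pair_key(a, b), cnt, envir = f2)
  }
  structure(list(N = N, f = f, f2 = f2), class = "fedkg_cooccurrence")
}

pair_key <- function(a, b) {
  paste(sort(c(a, b), method = "radix"), collapse = "|")
}

cooc_f <- function(table, x) {
  if (x %in% names(table$f)) table$f[[x]] else 0
}

cooc_f2 <- function(table, x, y) {
  k <- pair_key(x, y)
  if (exists(k, envir = table$f2, inherits = FALSE)) {
    get(k, envir = table$f2, inherits = FALSE)
  } else if (identical(x, y)) {
    cooc_f(table, x)  # self co-occurrence defaults to occurrence
  } else {
    0
  }
}

#' Normalized Google Distance between two terms
#'
#' \deqn{NGD(x, y) = \frac{\max(\log f(x), \log f(y)) - \log f(x, y)}
#'                        {\log N - \min(\log f(x), \log f(y))}}
#'
#' Symmetric, non-negative on well-formed tables, zero on identity when
#' `f(x, x) = f(x)`, and `+Inf` when the terms never co-occur
#' (`f(x, y) = 0`). Terms with zero occurrence count are undefined-term
#' errors.
#'
#' @param x,y CURIE strings.
#' @param table A `fedkg_cooccurrence`.
#' @return Non-negative numeric, possibly `Inf`.
#' @examples
#' \dontrun{ngd("NCBIGene:7157", "CHEBI:15365", table)}
#' @export
ngd <- function(x, y, table) {
  fx <- cooc_f(table, x)
  fy <- cooc_f(table, y)
  if (fx <= 0 || fy <= 0) {
    stop_fedkg("ngd undefined: zero occurrence count for '",
               if (fx <= 0) x else y, "'", class = "fedkg_undefined_term_error")
  }
  fxy <- cooc_f2(table, x, y)
  if (fxy <= 0) return(Inf)
  num <- max(log(fx), log(fy)) - log(fxy)
  den <- log(table$N) - min(log(fx), log(fy))
  if (den <= 0) return(Inf)
  max(0, num / den)
}

# Similarity in [0, 1]: 1 - NGD/cap, floored at 0; Inf -> 0.
ngd_similarity <- function(x, y, table, ngd_cap = 1) {
  d <- ngd(x, y, table)
  if (!is.finite(d)) return(0)
  max(0, 1 - d / ngd_cap)
}

#' Scoring configuration
#'
#' Weights for the three score components (path count, path length,
#' NGD similarity); non-negative, normalized to sum to one. `ngd_cap` is
#' the distance at which NGD similarity saturates to zero.
#'
#' @param w_paths,w_length,w_sim Component weights.
#' @param ngd_cap Positive saturation distance.
#' @return A `fedkg_score_config`.
#' @export
score_config <- function(w_paths = 1/3, w_length = 1/3, w_sim = 1/3,
                         ngd_cap = 1) {
  w <- c(w_paths, w_length, w_sim)
  if (any(w < 0) || sum(w) <= 0) {
    stop_fedkg("score weights must be non-negative with positive sum",
               class = "fedkg_config_error")
  }
  if (ngd_cap <= 0) {
    stop_fedkg("ngd_cap must be positive", class = "fedkg_config_error")
  }
  w <- w / sum(w)
  structure(list(w_paths = w[1], w_length = w[2], w_sim = w[3],
                 ngd_cap = ngd_cap),
            class = "fedkg_score_config")
}

# Component transforms: both map into [0, 1].
g_paths <- function(n) 1 - 1 / (1 + log(1 + n))
h_length <- function(L) 1 / max(1, L)

# Shortest qedge distance from each open qnode to the nearest pinned one.
path_lengths_from_pins <- function(query_graph) {
  pins <- pinned_qnodes(query_graph)
  open <- setdiff(names(query_graph$qnodes), pins)
  if (length(open) == 0) return(1)
  dist <- stats::setNames(rep(Inf, length(query_graph$qnodes)),
                          names(query_graph$qnodes))
  dist[pins] <- 0
  repeat {
    changed <- FALSE
    for (e in query_graph$qedges) {
      if (dist[[e$subject]] + 1 < dist[[e$object]]) {
        dist[[e$object]] <- dist[[e$subject]] + 1; changed <- TRUE
      }
      if (dist[[e$object]] + 1 < dist[[e$subject]]) {
        dist[[e$subject]] <- dist[[e$object]] + 1; changed <- TRUE
      }
    }
    if (!changed) break
  }
  mean(dist[open])
}

#' Score one assembled result
#'
#' Composite score over three factors: the number of supporting paths
#' (`n_paths` = distinct supporting records across all edge bindings,
#' through `g(n) = 1 - 1/(1 + ln(1 + n))`), the mean path length from the
#' pinned nodes (`h(L) = 1/L`, shortest qedge distance averaged over open
#' query nodes), and the mean NGD similarity over entity pairs adjacent in
#' the result. Entity pairs missing from the co-occurrence table are
#' skipped; with no computable pair the similarity component is zero. The
#' total `w_paths * g + w_length * h + w_sim * sim` lies in [0, 1], never
#' decreases when a supporting record is added, and never increases when
#' any pairwise NGD grows.
#'
#' @param result One result from [assemble()].
#' @param query_graph The `fedkg_query_graph`.
#' @param table A `fedkg_cooccurrence` (or `NULL`: similarity 0).
#' @param config A `fedkg_score_config`.
#' @return The result with a `score` element (`n_paths`,
#'   `mean_path_length`, `sim`, `total`).
#' @export
score_result <- function(result, query_graph, table = NULL,
                         config = score_config()) {
  n_paths <- length(unique(unlist(result$edge_bindings, use.names = FALSE)))
  mpl <- path_lengths_from_pins(query_graph)
  sims <- numeric(0)
  if (!is.null(table)) {
    for (e in query_graph$qedges) {
      a <- result$node_bindings[[e$subject]]
      b <- result$node_bindings[[e$object]]
      if (cooc_f(table, a) > 0 && cooc_f(table, b) > 0) {
        sims <- c(sims, ngd_similarity(a, b, table, config$ngd_cap))
      }
    }
  }
  sim <- if (length(sims) == 0) 0 else mean(sims)
  total <- config$w_paths * g_paths(n_paths) +
    config$w_length * h_length(mpl) +
    config$w_sim * sim
  result$score <- list(n_paths = n_paths, mean_path_length = mpl,
                       sim = sim, total = total)
  result
}

#' Score a list of assembled results
#'
#' @param results List from [assemble()].
#' @inheritParams score_result
#' @return List of scored results (unranked).
#' @export
score_results <- function(results, query_graph, table = NULL,
                          config = score_config()) {
  lapply(results, score_result, query_graph = query_graph, table = table,
         config = config)
}

#' Rank scored results
#'
#' Descending total score; ties broken by the lexicographic order of the
#' bound CURIEs (in query-node-id order), so ranking is deterministic and
#' invariant under permutation of the input list.
#'
#' @param results List of scored results.
#' @return The same results, ordered.
#' @export
rank_results <- function(results) {
  if (length(results) == 0) return(results)
  totals <- vapply(results, function(r) r$score$total, numeric(1))
  keys <- vapply(results, function(r) {
    nb <- r$node_bindings
    paste(unlist(nb[sort(names(nb), method = "radix")]), collapse = "|")
  }, character(1))
  results[order(-totals, keys, method = "radix")]
}
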