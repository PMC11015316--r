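test_that("generation is deterministic: same seed, byte-identical bundle", {
  p <- generation_params(seed = 7)
  b1 <- generate_network(p)
  b2 <- generate_network(p)
  expect_identical(b1$spec_docs, b2$spec_docs)
  expect_identical(b1$associations, b2$associations)
  expect_identical(b1$normalizer_clusters, b2$normalizer_clusters)
  expect_identical(b1$cooccurrence_doc, b2$cooccurrence_doc)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("generated bundles satisfy their structural invariants", {
  b <- generate_network(generation_params(seed = 11, fraction_synonyms = 0.3))
  ops <- unlist(lapply(b$specs, function(s) s$operations), recursive = FALSE)
  # association prefixes match each operation's annotation
  for (op in ops) {
    tab <- b$associations[[op$op_id]]
    if (nrow(tab) == 0) next
    expect_true(all(startsWith(tab$input, paste0(op$input_prefix, ":"))))
    expect_true(all(startsWith(tab$output, paste0(op$output_prefix, ":"))))
  }
  # co-occurrence invariants: f <= N, f2 <= min(f)
  tab <- b$cooccurrence
  expect_true(all(tab$f <= tab$N))
  for (k in ls(envir = tab$f2)) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    expect_lte(get(k, envir = tab$f2), min(tab$f[[ab[1]]], tab$f[[ab[2]]]))
  }
  # synonym fraction wired into the normalizer
  aliased <- b$entities$alias[!is.na(b$entities$alias)]
  expect_length(aliased, 3 * floor(0.3 * 20))
  for (a in aliased[1:3]) {
    expect_true(normalize_curie(a, b$normalizer)$normalized)
    expect_false(normalize_curie(a, b$normalizer)$curie == a)
  }
})

test_that("association totals concentrate around n_categories * n_entities * mean_out_degree", {
  b <- generate_network(generation_params(seed = 3, n_categories = 3,
                                          n_apis = 3,
                                          n_entities_per_category = 20,
                                          mean_out_degree = 2))
  total <- sum(vapply(b$associations, nrow, integer(1)))
  expected <- 3 * 20 * 2
  expect_lt(abs(total - expected), 3 * sqrt(expected))  # 3-sigma Poisson band
})

test_that("a zero out-degree network has specs but no associations, hence no multi-hop results", {
  b <- generate_network(generation_params(seed = 5, mean_out_degree = 0))
  expect_gt(length(b$specs), 0)
  expect_identical(sum(vapply(b$associations, nrow, integer(1))), 0L)
  q <- two_hop_query("Disease", "Gene", "ChemicalEntity",
                     pin = b$entities$curie[1])
  out <- run_query(bundle_registry(b), q, make_fixture_transport(b))
  expect_length(out$results, 0)
  expect_identical(nrow(ground_truth(b, q)), 0L)
})

test_that("infeasible parameters are rejected", {
  expect_error(generation_params(mean_out_degree = 50,
                                 n_entities_per_category = 20),
               class = "fedkg_param_error")
  expect_error(generation_params(n_categories = 0), class = "fedkg_param_error")
  expect_error(generation_params(fraction_synonyms = 1.5),
               class = "fedkg_param_error")
})

test_that("the fixture transport answers from association tables in the declared shape", {
  b <- generate_network(generation_params(seed = 13))
  tr <- make_fixture_transport(b)
  op <- b$specs[[1]]$operations[[1]]
  tab <- b$associations[[op$op_id]]
  inp <- tab$input[1]
  wanted <- unique(tab$output[tab$input == inp])
  req <- render_subquery(op, inp)[[1]]
  expect_identical(extract_ids(tr(req), op$response_id_path),
                   fedkg:::curie_local(wanted))

  # batched request of two inputs -> union of per-input outputs
  inp2 <- unique(tab$input)[1:2]
  req2 <- render_subquery(op, inp2, max_batch = 10)[[1]]
  union_out <- unique(tab$output[tab$input %in% inp2])
  expect_setequal(extract_ids(tr(req2), op$response_id_path),
                  fedkg:::curie_local(union_out))

  # a failing op returns a failure signal, never a document
  trf <- make_fixture_transport(b, failure_modes = op$op_id)
  expect_s3_class(trf(req), "fedkg_transport_failure")
})

test_that("oracle basics: pins echo back and unsatisfiable predicates yield nothing", {
  b <- generate_network(generation_params(seed = 21))
  pin <- b$entities$curie[1]
  single <- parse_query_graph(list(message = list(query_graph = list(
    nodes = list(n0 = list(ids = list(pin))),
    edges = structure(list(), names = character(0))))), b$hierarchy)
  gt <- ground_truth(b, single)
  expect_identical(gt$n0, pin)

  # no generated operation carries the bare root predicate
  qg <- parse_query_graph(list(message = list(query_graph = list(
    nodes = list(n0 = list(ids = list(pin), categories = list("Disease")),
                 n1 = list(categories = list("Gene"))),
    edges = list(e0 = list(subject = "n0", object = "n1",
                           predicates = list("treats")))))), b$hierarchy)
  expect_identical(nrow(ground_truth(b, qg)), 0L)
})

test_that("engine and oracle agree end to end on a seeded bundle", {
  b <- generate_network(generation_params(seed = 42))
  reg <- bundle_registry(b)
  tr <- make_fixture_transport(b)
  pins <- b$entities$curie[b$entities$category == "Disease"][1:2]
  q <- two_hop_query("Disease", "Gene", "ChemicalEntity", pin = pins)
  out <- run_query(reg, q, tr)
  got <- results_to_bindings(out$results, names(q$qnodes))
  want <- ground_truth(b, q)
  expect_identical(got, want)
  expect_gt(nrow(want), 0)  # the chain topology guarantees coverage
})
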