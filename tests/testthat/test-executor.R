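test_that("sub-query rendering substitutes, filters by prefix, and chunks by batch size", {
  h <- example_hierarchy()
  op <- parse_api_spec(make_spec_doc("T", list(
    make_op("op_t", "Disease", "Gene", "related_to", in_prefix = "MONDO",
            template = "ids={inputs}", max_batch = 2))), h)$operations$op_t

  one <- render_subquery(op, "MONDO:1017")
  expect_length(one, 1)
  expect_identical(one[[1]]$payload, "ids=1017")

  # 5 inputs at max_batch 2 -> requests of sizes 2, 2, 1
  reqs <- render_subquery(op, paste0("MONDO:", 1:5))
  expect_length(reqs, 3)
  expect_identical(vapply(reqs, function(r) length(r$inputs), integer(1)),
                   c(2L, 2L, 1L))
  expect_identical(reqs[[1]]$payload, "ids=1,2")
  expect_identical(reqs[[3]]$payload, "ids=5")

  # wrong-prefix inputs are filtered out; all wrong -> no requests
  expect_length(render_subquery(op, c("CHEBI:1", "CHEBI:2")), 0)
  mixed <- render_subquery(op, c("CHEBI:1", "MONDO:9"))
  expect_identical(mixed[[1]]$payload, "ids=9")
})

test_that("identifier extraction follows the path dialect and matches an independent recursive descent", {
  doc <- list(hits = list(list(id = "7157"), list(id = "1017")))
  expect_identical(extract_ids(doc, "hits[].id"), c("7157", "1017"))
  expect_identical(extract_ids(doc, "hits[].missing"), character(0))
  expect_identical(extract_ids(doc, "absent[].id"), character(0))
  # duplicates and order are preserved
  doc2 <- list(hits = list(list(id = "a"), list(id = "b"), list(id = "a")))
  expect_identical(extract_ids(doc2, "hits[].id"), c("a", "b", "a"))

  # nested arrays against the hand-written oracle
  nested <- list(a = list(b = list(
    list(c = list(list(id = "x1"), list(id = "x2"))),
    list(c = list(list(id = "y1"))),
    list(other = "ignored"))))
  path <- "a.b[].c[].id"
  expect_identical(extract_ids(nested, path), oracle_extract(nested, path))
  expect_identical(extract_ids(nested, path), c("x1", "x2", "y1"))

  # syntax errors are configuration errors at parse time
  expect_error(parse_id_path("hits[].["), class = "fedkg_config_error")
  expect_error(parse_id_path(""), class = "fedkg_config_error")
})

test_that("normalization maps equivalents to canonical form, is idempotent, and passes unknowns through", {
  reg <- example_registry()
  # Ensembl gene id -> NCBI gene id (cross-namespace translation)
  n <- normalize_curie("ENSEMBL:ENSG00000141510", reg$normalizer)
  expect_identical(n$curie, "NCBIGene:7157")
  expect_identical(n$label, "TP53")
  expect_true(n$normalized)
  # canonical input maps to itself
  expect_identical(normalize_curie("NCBIGene:7157", reg$normalizer)$curie,
                   "NCBIGene:7157")
  # unknown input passes through, flagged
  u <- normalize_curie("FOO:1", reg$normalizer)
  expect_identical(u$curie, "FOO:1")
  expect_false(u$normalized)
})

test_that("edge execution retrieves per-input records, keeps multi-API provenance, and isolates failures", {
  reg <- example_registry()
  qg <- parse_query_graph(file.path(example_dir(), "query_two_hop.json"),
                          reg$hierarchy)
  plan <- plan_query(qg, reg$metakg, reg$hierarchy)
  tr <- example_transport(reg)

  res <- execute_edge(plan$edges$e0, "e0",
                      list(subject = "MONDO:0005148", object = character(0)),
                      reg$metakg, tr, reg$normalizer)
  # CTD-like: 1017, 7157; Monarch-like: 7157, 5468 -> 4 records, and the
  # shared association is kept once per API (provenance in the dedup key)
  expect_identical(nrow(res$records), 4L)
  shared <- res$records[res$records$object == "NCBIGene:7157", ]
  expect_setequal(shared$op_id,
                  c("op_ctd_disease_gene", "op_monarch_disease_gene"))
  expect_identical(unique(res$records$subject), "MONDO:0005148")
  expect_identical(unique(res$records$subject_category), "Disease")

  # one API failing -> records from the healthy one plus a warning
  tr_fail <- example_transport(reg, failure_modes = "op_ctd_disease_gene")
  res_f <- execute_edge(plan$edges$e0, "e0",
                        list(subject = "MONDO:0005148", object = character(0)),
                        reg$metakg, tr_fail, reg$normalizer)
  expect_identical(sort(unique(res_f$records$op_id)), "op_monarch_disease_gene")
  expect_length(res_f$warnings, 1)
  expect_match(res_f$warnings, "op_ctd_disease_gene")
  expect_identical(res_f$attempts$status[res_f$attempts$op_id ==
                                           "op_ctd_disease_gene"], "failed")

  # pinned identifiers in a non-canonical namespace are converted before filtering
  res_alias <- execute_edge(plan$edges$e0, "e0",
                            list(subject = "DOID:9352", object = character(0)),
                            reg$metakg, tr, reg$normalizer)
  expect_identical(nrow(res_alias$records), 4L)
  expect_identical(unique(res_alias$records$subject), "MONDO:0005148")
})

test_that("plan execution chains hops, propagates emptiness, and is deterministic", {
  reg <- example_registry()
  qg <- parse_query_graph(file.path(example_dir(), "query_two_hop.json"),
                          reg$hierarchy)
  plan <- plan_query(qg, reg$metakg, reg$hierarchy)
  tr <- example_transport(reg)

  rs1 <- execute_plan(plan, qg, tr, reg$metakg, reg$normalizer)
  rs2 <- execute_plan(plan, qg, tr, reg$metakg, reg$normalizer)
  expect_identical(rs1$records, rs2$records)  # fixture transport is pure

  # e1 inputs are exactly the genes retrieved by e0
  e0_genes <- sort(unique(rs1$records$object[rs1$records$qedge_id == "e0"]))
  e1_inputs <- sort(unique(rs1$records$subject[rs1$records$qedge_id == "e1"]))
  expect_true(all(e1_inputs %in% e0_genes))
  expect_identical(nrow(rs1$records), 7L)

  # provenance closure: every record cites a planned op for its qedge
  for (eid in unique(rs1$records$qedge_id)) {
    expect_true(all(rs1$records$op_id[rs1$records$qedge_id == eid] %in%
                      plan$edges[[eid]]$op_id))
  }

  # a pin with no associations yields an empty but well-formed record set
  qg_empty <- parse_query_graph(list(message = list(query_graph = list(
    nodes = list(n0 = list(ids = list("MONDO:9999999"),
                           categories = list("Disease")),
                 n1 = list(categories = list("Gene")),
                 n2 = list(categories = list("ChemicalEntity"))),
    edges = list(e0 = list(subject = "n0", object = "n1"),
                 e1 = list(subject = "n1", object = "n2"))))), reg$hierarchy)
  rs_e <- execute_plan(plan_query(qg_empty, reg$metakg, reg$hierarchy),
                       qg_empty, tr, reg$metakg, reg$normalizer)
  expect_identical(nrow(rs_e$records), 0L)
  expect_s3_class(rs_e$records, "data.frame")

  # normalization idempotence: re-normalizing the record set changes nothing
  renorm <- vapply(rs1$records$subject, function(c)
    normalize_curie(c, reg$normalizer)$curie, character(1), USE.NAMES = FALSE)
  expect_identical(renorm, rs1$records$subject)
})

test_that("the fixture transport distinguishes unknown operations from empty results", {
  reg <- example_registry()
  tr <- example_transport(reg)
  op <- reg$metakg$operations$op_ctd_disease_gene
  # unknown route -> transport error
  expect_error(tr(list(server_url = "https://nowhere.example.org",
                       path = "/x", method = "GET", payload = "q=1")),
               class = "fedkg_transport_error")
  # known route, unknown input -> empty document, no error
  resp <- tr(list(server_url = op$server_url, path = op$path, method = "GET",
                  payload = "q=0000000"))
  expect_identical(extract_ids(resp, op$response_id_path), character(0))
})
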