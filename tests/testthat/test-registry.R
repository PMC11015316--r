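test_that("curies split on the first colon and reject malformed input", {
  expect_identical(parse_curie("NCBIGene:1017")[c("prefix", "local_id")],
                   list(prefix = "NCBIGene", local_id = "1017"))
  expect_identical(parse_curie("CHEBI:15365")$local_id, "15365")
  # extra colons stay in the local id
  expect_identical(parse_curie("GO:BP:0008150")$local_id, "BP:0008150")
  expect_error(parse_curie("geneID"), class = "fedkg_format_error")
  expect_error(parse_curie(":x"), class = "fedkg_format_error")
  expect_error(parse_curie("x:"), class = "fedkg_format_error")
})

test_that("api specs parse with all annotation fields and validate against the vocabulary", {
  h <- example_hierarchy()
  spec <- parse_api_spec(file.path(example_dir(), "ctd_like.json"), h)
  expect_identical(spec$api_name, "CTD-like API")
  expect_length(spec$operations, 1)
  op <- spec$operations[["op_ctd_disease_gene"]]
  expect_identical(op$input_category, "Disease")
  expect_identical(op$input_prefix, "MONDO")
  expect_identical(op$predicate, "condition_associated_with_gene")
  expect_identical(op$output_category, "Gene")
  expect_identical(op$output_prefix, "NCBIGene")
  expect_identical(op$method, "GET")
  expect_identical(op$request_template, "q={inputs}")
  expect_identical(attr(op$response_id_path, "source"), "hits[].id")
  expect_identical(op$max_batch, 3L)

  # empty spec: zero annotated endpoints is legal
  empty <- parse_api_spec(make_spec_doc("Empty API", list()), h)
  expect_length(empty$operations, 0)

  # yaml input is accepted too
  yml <- paste(
    "info:", "  title: YAML API", "  version: '2.0'",
    "servers:", "  - url: https://y.example.org",
    "paths:", "  /assoc:", "    x-kg-operations:",
    "      - op_id: op_y", "        input_category: Gene",
    "        input_prefix: NCBIGene", "        predicate: interacts_with",
    "        output_category: ChemicalEntity", "        output_prefix: CHEBI",
    "        method: GET", "        request_template: q={inputs}",
    "        response_id_path: hits[].id", sep = "\n")
  yspec <- parse_api_spec(yml, h)
  expect_identical(yspec$operations$op_y$output_prefix, "CHEBI")
  expect_identical(yspec$operations$op_y$max_batch, 100L)  # dialect default
})

test_that("validation errors name the field and operation", {
  h <- example_hierarchy()
  bad_tpl <- make_spec_doc("Bad API", list(
    make_op("op_bad", "Disease", "Gene", "related_to", template = "q=stuff")))
  expect_error(parse_api_spec(bad_tpl, h), "op_bad",
               class = "fedkg_validation_error")
  bad_cat <- make_spec_doc("Bad API", list(
    make_op("op_cat", "Klingon", "Gene", "related_to")))
  expect_error(parse_api_spec(bad_cat, h), "Klingon",
               class = "fedkg_validation_error")
  missing <- make_spec_doc("Bad API", list(
    within(make_op("op_m", "Disease", "Gene", "related_to"),
           rm(response_id_path))))
  expect_error(parse_api_spec(missing, h), "response_id_path",
               class = "fedkg_validation_error")
  bad_pred <- make_spec_doc("Bad API", list(
    make_op("op_p", "Disease", "Gene", "not_a_predicate")))
  expect_error(parse_api_spec(bad_pred, h), class = "fedkg_validation_error")
})

test_that("parsing is deterministic and specs round-trip through serialization", {
  h <- example_hierarchy()
  for (f in c("ctd_like.json", "monarch_like.json", "mychem_like.json")) {
    path <- file.path(example_dir(), f)
    s1 <- parse_api_spec(path, h)
    s2 <- parse_api_spec(path, h)
    expect_identical(s1, s2)
    expect_equal(parse_api_spec(serialize_api_spec(s1), h), s1)
  }
})

test_that("meta-KG edge count equals total operations and duplicates are fatal", {
  h <- example_hierarchy()
  expect_identical(nrow(build_meta_kg(list())$edges), 0L)
  expect_length(build_meta_kg(list())$categories, 0)

  # two specs with 2 and 3 operations over 3 categories -> 3 categories, 5 edges
  spec_a <- parse_api_spec(make_spec_doc("API A", list(
    make_op("a1", "Disease", "Gene", "related_to"),
    make_op("a2", "Gene", "Disease", "related_to"))), h)
  spec_b <- parse_api_spec(make_spec_doc("API B", list(
    make_op("b1", "Disease", "Gene", "related_to"),
    make_op("b2", "Gene", "ChemicalEntity", "interacts_with"),
    make_op("b3", "ChemicalEntity", "Disease", "treats"))), h)
  kg <- build_meta_kg(list(spec_a, spec_b))
  expect_identical(nrow(kg$edges), 5L)
  expect_setequal(kg$categories, c("Disease", "Gene", "ChemicalEntity"))

  # conservation: removing one spec removes exactly its operations' edges
  kg_a <- build_meta_kg(list(spec_a))
  expect_identical(nrow(kg_a$edges), 2L)
  expect_setequal(setdiff(kg$edges$op_id, kg_a$edges$op_id),
                  c("b1", "b2", "b3"))

  dup <- parse_api_spec(make_spec_doc("API C", list(
    make_op("a1", "Gene", "Gene", "related_to"))), h)
  expect_error(build_meta_kg(list(spec_a, dup)), "a1",
               class = "fedkg_validation_error")
})

test_that("meta-KG summary counts distinct APIs per pair and tallies to the edge total", {
  expect_identical(nrow(meta_kg_summary(build_meta_kg(list()))), 0L)
  reg <- example_registry()
  s <- meta_kg_summary(reg$metakg)
  dg <- s[s$subject_category == "Disease" & s$object_category == "Gene", ]
  expect_identical(dg$n_apis, 2L)  # CTD-like and Monarch-like both serve it
  expect_identical(sum(s$n_operations), nrow(reg$metakg$edges))

  # random registries: summary equals a brute-force tally over operations
  set.seed(401)
  h <- example_hierarchy()
  for (i in 1:10) {
    kg <- random_registry(h)
    s <- meta_kg_summary(kg)
    expect_identical(sum(s$n_operations), nrow(kg$edges))
    expect_true(all(s$n_apis <= length(unique(kg$edges$api_name))))
    for (j in seq_len(nrow(s))) {
      sel <- kg$edges$subject_category == s$subject_category[j] &
        kg$edges$object_category == s$object_category[j]
      expect_identical(s$n_operations[j], sum(sel))
      expect_identical(s$n_apis[j], length(unique(kg$edges$api_name[sel])))
    }
  }
})

test_that("registry config checks paths and resolves them relative to the config", {
  reg <- example_registry()
  expect_s3_class(reg$metakg, "fedkg_metakg")
  expect_identical(nrow(reg$metakg$edges), 3L)
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(specs = list("nope.json"),
                                   hierarchy = "h.txt", normalizer = "n.json",
                                   cooccurrence = "c.json"),
                              auto_unbox = TRUE), tf)
  expect_error(load_registry_config(tf), class = "fedkg_config_error")
})
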