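test_that("merging with an empty message is the identity", {
  m <- toy_message()
  empty <- kg_message(query_graph(), NULL, NULL)
  merged <- merge_messages(list(m, empty), m$query_graph, the_model)
  expect_identical(write_message(merged), write_message(m))
})

test_that("node union preserves provenance; edges keep per-source copies", {
  qg <- query_graph(tibble::tibble(alias = "gene", concept = "gene"))
  mk <- function(src, attrs) {
    kg <- knowledge_graph(
      nodes = tibble::tibble(id = c("X:1", "X:2"), concept = "gene",
                             label = c("g1", "g2"),
                             attributes = list(attrs, list()),
                             sources = list(src, src)),
      edges = tibble::tibble(subject = "X:1", object = "X:2",
                             predicate = "interacts_with", source = src))
    kg_message(qg, kg, tibble::tibble(
      node_bindings = list(c(gene = "X:1")), edge_bindings = list(list()),
      score = NA_real_))
  }
  merged <- merge_messages(list(mk("s1", list(a = 1)),
                                mk("s2", list(a = 2, b = 3))),
                           qg, the_model)
  n1 <- merged$knowledge_graph$nodes
  expect_identical(nrow(n1), 2L)  # one node per id
  expect_identical(n1$sources[[which(n1$id == "X:1")]], c("s1", "s2"))
  # same (subject, predicate, object) from two services stays two edges
  expect_identical(nrow(merged$knowledge_graph$edges), 2L)
  expect_setequal(merged$knowledge_graph$edges$source, c("s1", "s2"))
  # last writer wins with an audit trail of the displaced value
  attrs <- n1$attributes[[which(n1$id == "X:1")]]
  expect_identical(attrs$a, 2)
  expect_identical(attrs$attribute_provenance, "a=1")
})

test_that("incompatible concept assertions for one id are a merge error", {
  qg <- query_graph(tibble::tibble(alias = "x", concept = "named_thing"))
  mk <- function(src, concept) {
    kg <- knowledge_graph(tibble::tibble(
      id = "X:1", concept = concept, sources = list(src)))
    kg_message(qg, kg, tibble::tibble(
      node_bindings = list(c(x = "X:1")), edge_bindings = list(list()),
      score = NA_real_))
  }
  expect_error(
    merge_messages(list(mk("s1", "gene"), mk("s2", "disease")), qg, the_model),
    "incompatible", class = "kgql_merge_error")
  # compatible under subtype: keeps the more specific concept
  merged <- merge_messages(list(mk("s1", "chemical_substance"),
                                mk("s2", "drug")), qg, the_model)
  expect_identical(merged$knowledge_graph$nodes$concept, "drug")
})

test_that("stitching joins rows on the shared alias with cross-counting", {
  qg_full <- query_graph(
    nodes = tibble::tibble(alias = c("a", "b", "c"),
                           concept = "named_thing"),
    edges = tibble::tibble(from_alias = c("a", "b"), to_alias = c("b", "c"),
                           predicate = NA_character_))
  seg_msg <- function(aliases, rows, kg_ids) {
    qg <- query_graph(
      nodes = tibble::tibble(alias = aliases, concept = "named_thing"),
      edges = tibble::tibble(from_alias = aliases[1], to_alias = aliases[2],
                             predicate = NA_character_))
    kg <- knowledge_graph(tibble::tibble(id = kg_ids, concept = "gene"))
    kg_message(qg, kg, tibble::tibble(
      node_bindings = rows, edge_bindings = rep(list(list()), length(rows)),
      score = NA_real_))
  }
  up <- seg_msg(c("a", "b"),
                list(c(a = "N:a1", b = "N:b1"), c(a = "N:a2", b = "N:b1"),
                     c(a = "N:a3", b = "N:b9")),
                c("N:a1", "N:a2", "N:a3", "N:b1", "N:b9"))
  down <- seg_msg(c("b", "c"),
                  list(c(b = "N:b1", c = "N:c1"), c(b = "N:b1", c = "N:c2"),
                       c(b = "N:b1", c = "N:c3")),
                  c("N:b1", "N:c1", "N:c2", "N:c3"))
  km <- stitch_answers(list(up, down), qg_full)
  # 2 upstream rows on N:b1 x 3 downstream rows = 6; N:b9 row is dropped
  expect_identical(nrow(km), 6L)
  expect_false(any(grepl("N:b9", binding_strings(km))))
})

test_that("stitched answers equal brute-force enumeration on random cases", {
  for (seed in 1:15) {
    fed <- random_federation(seed + 100, n_sources = 2, n_concepts = 4,
                             n_nodes = 4, edge_density = 0.5)
    q <- random_path_query(fed, seed + 3000, n_hops = 3)
    schema <- merge_schema(fetch_transition_maps(fed$registry))
    plan <- tryCatch(plan_query(q, schema, the_model),
                     kgql_plan_error = function(e) NULL)
    if (is.null(plan)) next
    ex <- execute_plan(plan, fed$registry, model = the_model)
    expect_identical(
      binding_strings(ex$merged$knowledge_map),
      binding_strings(oracle_answers(q, fed$union_kg, the_model)),
      label = paste("seed", seed))
  }
})

test_that("merge is idempotent and order-insensitive on graph content", {
  m <- random_message(42)
  twice <- merge_messages(list(m, m), m$query_graph, the_model)
  expect_identical(twice$knowledge_graph, m$knowledge_graph)
  expect_identical(binding_strings(twice$knowledge_map),
                   binding_strings(m$knowledge_map))
})

test_that("JSONPath extraction returns match lists and flags bad syntax", {
  kg <- knowledge_graph(tibble::tibble(
    id = c("A:1", "A:2", "A:3"), concept = "gene"))
  qg <- query_graph(tibble::tibble(alias = "gene", concept = "gene"))
  msg <- kg_message(qg, kg, NULL)
  ids <- extract_variable(msg, "$.knowledge_graph.nodes[*].id")
  expect_identical(unlist(ids), c("A:1", "A:2", "A:3"))
  expect_identical(extract_variable(msg, "$.knowledge_graph.nodes[1].id")[[1]],
                   "A:2")  # JSONPath indexes from zero
  expect_identical(extract_variable(msg, "$.no.such.path"), list())
  expect_error(extract_variable(msg, "$[unclosed"),
               class = "kgql_expression_error")
  expect_error(extract_variable(msg, "nodes.id"),
               class = "kgql_expression_error")
  # whole-graph marker
  expect_identical(extract_variable(msg, NULL), kg)
})

test_that("the named-graph store round-trips, warns on overwrite", {
  dir <- withr::local_tempdir()
  store <- named_graph_store(dir)
  kg <- toy_kg()
  store_named_graph(store, "answers", kg)
  expect_identical(load_named_graph(store, "answers"), kg)
  expect_true(file.exists(file.path(dir, "answers.json")))
  expect_warning(store_named_graph(store, "answers", empty_graph <-
                                     knowledge_graph()),
                 class = "kgql_overwrite_warning")
  expect_identical(nrow(load_named_graph(store, "answers")$nodes), 0L)
  # reload from the backing file alone
  store2 <- named_graph_store(dir)
  expect_identical(nrow(load_named_graph(store2, "answers")$nodes), 0L)
  expect_error(load_named_graph(store, "missing"),
               class = "kgql_lookup_error")
})

test_that("filters: full-range identity, weight rule, source checkbox", {
  msg <- toy_message()
  expect_identical(write_message(apply_filters(msg, filter_settings())),
                   write_message(msg))

  # weights {0.7, NA, 0.2, 0.9}: range [0.5, 1] keeps 0.7, 0.9 and NA (as 1.0)
  f <- apply_filters(msg, filter_settings(edge_weight_range = c(0.5, 1)))
  w <- f$knowledge_graph$edges$weight
  expect_identical(sum(is.na(w)), 1L)
  expect_setequal(w[!is.na(w)], c(0.7, 0.9))

  f2 <- apply_filters(msg, filter_settings(allowed_sources = "beta"))
  expect_true(all(f2$knowledge_graph$edges$source == "beta"))
  # the answer row rode on an alpha edge, so it is dropped
  expect_identical(nrow(f2$knowledge_map), 0L)

  expect_error(filter_settings(edge_weight_range = c(0.9, 0.2)),
               class = "kgql_settings_error")
  expect_error(filter_settings(connectivity_range = c(-1, 2)),
               class = "kgql_settings_error")
})

test_that("connectivity filter uses pre-filter degrees and drops incident edges", {
  msg <- toy_message()
  # degrees: T:d1 = 3 (incl. self-loop 2), T:g1 = 2, T:c1 = 2, T:d2 = 1, iso = 0
  f <- apply_filters(msg, filter_settings(connectivity_range = c(1, 2)))
  expect_false("T:d1" %in% f$knowledge_graph$nodes$id)   # degree 3 via loop
  expect_false("T:iso" %in% f$knowledge_graph$nodes$id)  # degree 0
  expect_true(all(c("T:g1", "T:c1", "T:d2") %in% f$knowledge_graph$nodes$id))
  expect_false(any(f$knowledge_graph$edges$subject == "T:d1" |
                     f$knowledge_graph$edges$object == "T:d1"))
})

test_that("tightening ranges never adds elements, and output always validates", {
  for (seed in c(3, 17)) {
    msg <- random_message(seed)
    wide <- apply_filters(msg, filter_settings(
      edge_weight_range = c(0.1, 0.9), connectivity_range = c(0, 50)))
    narrow <- apply_filters(msg, filter_settings(
      edge_weight_range = c(0.3, 0.7), connectivity_range = c(1, 20)))
    expect_true(all(narrow$knowledge_graph$nodes$id %in%
                      wide$knowledge_graph$nodes$id))
    expect_true(all(edge_key(narrow$knowledge_graph$edges) %in%
                      edge_key(wide$knowledge_graph$edges)))
    # both already passed construction-time validation; assert explicitly
    expect_silent(kgql:::validate_message(wide))
    expect_silent(kgql:::validate_message(narrow))
  }
})

test_that("the tabular view is deterministic with one column per alias", {
  x <- run_use_case(1)
  tb <- to_table(x$res$message)
  expect_identical(nrow(tb), 13L)
  expect_identical(names(tb), c("cohort", "disease", "gene",
                                "chemical_substance"))
  expect_true(all(grepl("^PTH \\(FIX:PTH\\)$", tb$gene)))
  expect_identical(tb, tb[order(tb$cohort, tb$disease, tb$gene,
                                tb$chemical_substance), ])
  empty <- kg_message(x$res$message$query_graph, NULL, NULL, validate = FALSE)
  expect_identical(nrow(to_table(empty)), 0L)
  expect_identical(names(to_table(empty)), names(tb))
})

test_that("tidy and glance summarize a message the broom way", {
  x <- run_use_case(2)
  td <- generics::tidy(x$res$message)
  expect_identical(nrow(td), 17L)
  expect_true(all(c("cohort", "disease", "gene", "chemical_substance",
                    "score") %in% names(td)))
  gl <- generics::glance(x$res$message)
  expect_identical(gl$n_answers, 17L)
  expect_identical(gl$n_sources, 2L)
})
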