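uc1_robokop_segment <- function(pin = "FIX:ovarian_cancer") {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("disease", "gene", "chemical_substance"), the_model,
                  pinned = list(disease = pin))
  plan <- plan_query(q, schema, the_model)
  list(fed = fed, segment = plan$segments[[1]])
}

test_that("invoking a source binds every fragment alias with provenance", {
  x <- uc1_robokop_segment()
  msg <- invoke_source(x$fed$registry$sources$robokop, x$segment,
                       model = the_model)
  expect_identical(nrow(msg$knowledge_map), 13L)
  labels <- stats::setNames(msg$knowledge_graph$nodes$label,
                            msg$knowledge_graph$nodes$id)
  genes <- unique(vapply(msg$knowledge_map$node_bindings,
                         function(b) labels[[b[["gene"]]]], character(1)))
  expect_identical(genes, "PTH")
  chems <- vapply(msg$knowledge_map$node_bindings,
                  function(b) labels[[b[["chemical_substance"]]]], character(1))
  expect_setequal(chems, kgql:::UC1_CHEMICALS)
  expect_true(all(msg$knowledge_graph$edges$source == "robokop"))
})

test_that("pinning to an id absent from the shard yields an empty answer set", {
  x <- uc1_robokop_segment(pin = "FIX:not_a_disease")
  msg <- invoke_source(x$fed$registry$sources$robokop, x$segment,
                       model = the_model)
  expect_identical(nrow(msg$knowledge_map), 0L)
})

test_that("contract-violating responses are quarantined", {
  x <- uc1_robokop_segment()
  frag <- x$segment$sub_path

  bad_kg <- function(edit) {
    good <- x$fed$registry$sources$robokop$invoke(frag, list())
    edit(good)
  }
  rigged <- function(response) {
    knowledge_source("robokop",
                     x$fed$registry$sources$robokop$capabilities,
                     invoke = function(fragment, options) response)
  }

  # edge without the source stamp
  no_stamp <- bad_kg(function(m) {
    m$knowledge_graph$edges$source <- NA_character_
    kg_message(m$query_graph, m$knowledge_graph, NULL, validate = FALSE)
  })
  expect_error(invoke_source(rigged(no_stamp), x$segment, model = the_model),
               "provenance stamp", class = "kgql_federation_error")

  # binding with an incompatible concept
  wrong_concept <- bad_kg(function(m) {
    m$knowledge_graph$nodes$concept[
      m$knowledge_graph$nodes$id == "FIX:PTH"] <- "phenotypic_feature"
    m
  })
  expect_error(invoke_source(rigged(wrong_concept), x$segment,
                             model = the_model),
               "bound to query concept", class = "kgql_federation_error")

  # dangling edge endpoint
  dangling <- bad_kg(function(m) {
    kg <- m$knowledge_graph
    kg$edges$object[1] <- "FIX:ghost"
    structure(list(query_graph = m$query_graph, knowledge_graph = kg,
                   knowledge_map = m$knowledge_map), class = "kg_message")
  })
  expect_error(invoke_source(rigged(dangling), x$segment, model = the_model),
               class = "kgql_federation_error")

  # binding outside the pinned ids
  off_pin <- bad_kg(function(m) m)
  seg2 <- x$segment
  seg2$sub_path$nodes$pinned_ids[[2]] <- "FIX:some_other_gene"
  expect_error(invoke_source(rigged(off_pin), seg2, model = the_model),
               "pinned ids", class = "kgql_federation_error")
})

test_that("execution propagates bindings forward segment by segment", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("population_of_individual_organisms", "disease",
                    "gene", "chemical_substance"), the_model)
  plan <- plan_query(q, schema, the_model)
  ex <- execute_plan(plan, fed$registry, model = the_model)
  expect_length(ex$segments, 2)
  up_ids <- sort(unique(vapply(ex$segments[[1]]$knowledge_map$node_bindings,
                               function(b) b[["disease"]], character(1))))
  down_ids <- unique(vapply(ex$segments[[2]]$knowledge_map$node_bindings,
                            function(b) b[["disease"]], character(1)))
  # soundness: everything bound downstream at the join alias came from upstream
  expect_true(all(down_ids %in% up_ids))
})

test_that("an empty upstream segment short-circuits downstream invocation", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("population_of_individual_organisms", "disease",
                    "gene", "chemical_substance"), the_model,
                  pinned = list(population_of_individual_organisms = "FIX:nope"))
  plan <- plan_query(q, schema, the_model)
  before <- invocation_counts(fed$registry)
  ex <- execute_plan(plan, fed$registry, model = the_model)
  after <- invocation_counts(fed$registry)
  expect_identical(after[["robokop"]], before[["robokop"]])
  expect_identical(after[["icees"]], before[["icees"]] + 1L)
  expect_identical(nrow(ex$merged$knowledge_map), 0L)
})

test_that("unregistered services are a registry error", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("disease", "gene"), the_model, service = "/elsewhere")
  plan <- plan_query(q, schema, the_model)
  expect_error(execute_plan(plan, fed$registry, model = the_model),
               class = "kgql_registry_error")
})

test_that("the cache serves byte-identical queries without source calls", {
  fed <- build_use_case(1)
  cache <- query_cache()
  run_program(fed$query_text, fed$registry, model = the_model, cache = cache)
  c1 <- invocation_counts(fed$registry)
  expect_identical(cache_size(cache), 1L)

  r2 <- run_program(fed$query_text, fed$registry, model = the_model,
                    cache = cache)
  expect_identical(invocation_counts(fed$registry), c1)  # zero new calls
  expect_identical(nrow(r2$message$knowledge_map), 13L)

  # one character of whitespace circumvents the cache
  run_program(paste0(fed$query_text, "\n"), fed$registry, model = the_model,
              cache = cache)
  expect_true(all(invocation_counts(fed$registry) > c1))
})

test_that("cache control: disable keeps entries but stops serving/storing", {
  fed <- build_use_case(1)
  cache <- query_cache()
  run_program(fed$query_text, fed$registry, model = the_model, cache = cache)
  n1 <- cache_size(cache)

  cache_control(cache, "disable")
  c1 <- invocation_counts(fed$registry)
  run_program(fed$query_text, fed$registry, model = the_model, cache = cache)
  expect_identical(cache_size(cache), n1)  # disabled run stored nothing
  expect_true(all(invocation_counts(fed$registry) > c1))  # and re-executed

  cache_control(cache, "enable")
  c2 <- invocation_counts(fed$registry)
  run_program(fed$query_text, fed$registry, model = the_model, cache = cache)
  expect_identical(invocation_counts(fed$registry), c2)  # served again

  cache_control(cache, "clear")
  expect_identical(cache_size(cache), 0L)
  run_program(fed$query_text, fed$registry, model = the_model, cache = cache)
  expect_true(all(invocation_counts(fed$registry) > c2))  # miss after clear
})

test_that("caching is transparent to the final merged message", {
  fed_a <- build_use_case(1)
  cache <- query_cache()
  run_program(fed_a$query_text, fed_a$registry, model = the_model,
              cache = cache)
  cached <- run_program(fed_a$query_text, fed_a$registry, model = the_model,
                        cache = cache)
  fed_b <- build_use_case(1)
  uncached <- run_program(fed_b$query_text, fed_b$registry,
                          model = the_model, cache = NULL)
  expect_identical(write_message(cached$message),
                   write_message(uncached$message))
})
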