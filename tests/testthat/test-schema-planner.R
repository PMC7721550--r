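test_that("fixture sources advertise the expected transition maps", {
  fed <- build_use_case(1)
  maps <- fetch_transition_maps(fed$registry)
  icees <- maps[[which(purrr::map_chr(maps, "service") == "icees")]]
  expect_true(any(
    icees$transitions$source_concept == "population_of_individual_organisms" &
      icees$transitions$target_concept == "disease"))
  robokop <- maps[[which(purrr::map_chr(maps, "service") == "robokop")]]
  expect_true(any(robokop$transitions$source_concept == "gene" &
                    robokop$transitions$target_concept == "disease"))
  expect_true(any(robokop$transitions$source_concept == "gene" &
                    robokop$transitions$target_concept == "chemical_substance"))
  expect_length(fetch_transition_maps(source_registry()), 0)
})

test_that("transition maps validate names against the model", {
  expect_error(
    transition_map("x", tibble::tibble(source_concept = "nope",
                                       target_concept = "gene",
                                       predicate = "affects"), the_model),
    "unknown concept"
  )
  expect_error(
    transition_map("x", tibble::tibble(source_concept = "gene",
                                       target_concept = "disease",
                                       predicate = NA_character_), the_model),
    "no predicate"
  )
})

test_that("schema merge is the tuple union, retaining per-service copies", {
  tm1 <- transition_map("a", tibble::tibble(
    source_concept = "gene", target_concept = "disease",
    predicate = "gene_associated_with_condition"), the_model)
  tm2 <- transition_map("b", tibble::tibble(
    source_concept = c("gene", "gene"),
    target_concept = c("disease", "chemical_substance"),
    predicate = c("gene_associated_with_condition", "interacts_with")),
    the_model)
  s <- merge_schema(list(tm1, tm2))
  expect_identical(sort(s$services), c("a", "b"))
  expect_identical(nrow(s$transitions), 3L)
  shared <- s$transitions[s$transitions$target_concept == "disease", ]
  expect_identical(sort(shared$service), c("a", "b"))  # both copies kept

  s0 <- merge_schema(list())
  expect_identical(nrow(s0$transitions), 0L)
})

test_that("the worked-example path plans into two coalesced segments", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("population_of_individual_organisms", "disease",
                    "gene", "chemical_substance"), the_model)
  plan <- plan_query(q, schema, the_model)
  expect_length(plan$segments, 2)
  expect_identical(plan$segments[[1]]$service, "icees")
  expect_identical(plan$segments[[2]]$service, "robokop")
  expect_identical(plan$segments[[1]]$sub_path$nodes$alias,
                   c("population_of_individual_organisms", "disease"))
  expect_identical(plan$segments[[2]]$sub_path$nodes$alias,
                   c("disease", "gene", "chemical_substance"))
  expect_identical(plan$segments[[2]]$join_alias, "disease")
  expect_null(plan$segments[[1]]$join_alias)
})

test_that("a concrete service reference bypasses planning", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("disease", "gene"), the_model, service = "/robokop")
  plan <- plan_query(q, schema, the_model)
  expect_length(plan$segments, 1)
  expect_identical(plan$segments[[1]]$service, "robokop")
})

test_that("unsupported steps raise a planning error naming the step", {
  fed <- build_use_case(1)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  q <- path_query(c("gene", "environmental_feature"), the_model)
  err <- tryCatch(plan_query(q, schema, the_model), condition = function(e) e)
  expect_s3_class(err, "kgql_plan_error")
  expect_match(conditionMessage(err), "gene")
  expect_match(conditionMessage(err), "environmental_feature")
})

test_that("plans are deterministic, cover the path, and match the unique assignment", {
  for (seed in 1:20) {
    fed <- random_federation(seed, n_sources = 1 + seed %% 3,
                             n_concepts = 4, n_nodes = 3, edge_density = 0.5)
    schema <- merge_schema(fetch_transition_maps(fed$registry))
    q <- random_path_query(fed, seed + 2000, n_hops = 2 + seed %% 3)
    plan1 <- tryCatch(plan_query(q, schema, the_model),
                      kgql_plan_error = function(e) NULL)
    if (is.null(plan1)) next
    plan2 <- plan_query(q, schema, the_model)
    expect_identical(plan1, plan2)  # determinism

    # coverage: segment sub-paths partition the query edges in order
    covered <- purrr::map_dfr(plan1$segments, function(s) s$sub_path$edges)
    expect_identical(tibble::as_tibble(covered),
                     tibble::as_tibble(q$query_graph$edges))

    # single-source transitions: exhaustive per-edge candidate search must
    # agree with the planner's choice
    qg <- q$query_graph
    chosen <- unlist(purrr::map(plan1$segments, function(s)
      rep(s$service, nrow(s$sub_path$edges))))
    for (i in seq_len(nrow(qg$edges))) {
      cand <- kgql:::edge_candidates(schema, the_model,
                                     qg$nodes$concept[i],
                                     qg$nodes$concept[i + 1],
                                     qg$edges$predicate[i])
      expect_length(cand, 1)
      expect_identical(chosen[i], cand)
    }
  }
})

test_that("single-source federations always yield single-segment plans", {
  fed <- random_federation(11, n_sources = 1, n_concepts = 4, n_nodes = 3,
                           edge_density = 0.6)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  for (seed in 1:10) {
    q <- random_path_query(fed, seed, n_hops = 3)
    plan <- tryCatch(plan_query(q, schema, the_model),
                     kgql_plan_error = function(e) NULL)
    if (!is.null(plan)) expect_length(plan$segments, 1)
  }
})
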