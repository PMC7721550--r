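# Shared fixtures, all built in code.

the_model <- default_concept_model()

# Small hand-built graph: two diseases, a gene, a chemical; one self-loop.
toy_kg <- function() {
  knowledge_graph(
    nodes = tibble::tibble(
      id = c("T:d1", "T:d2", "T:g1", "T:c1", "T:iso"),
      concept = c("disease", "disease", "gene", "chemical_substance",
                  "phenotypic_feature"),
      label = c("disease one", "disease two", "gene one", "chem one",
                "isolated")
    ),
    edges = tibble::tibble(
      subject = c("T:g1", "T:g1", "T:d1", "T:d2"),
      object = c("T:d1", "T:c1", "T:d1", "T:c1"),
      predicate = c("gene_associated_with_condition", "interacts_with",
                    "related_to", "interacts_with"),
      weight = c(0.7, NA, 0.2, 0.9),
      source = c("alpha", "alpha", "beta", "beta")
    )
  )
}

toy_message <- function() {
  kg <- toy_kg()
  qg <- query_graph(
    nodes = tibble::tibble(alias = c("disease", "gene"),
                           concept = c("disease", "gene")),
    edges = tibble::tibble(from_alias = "disease", to_alias = "gene",
                           predicate = NA_character_)
  )
  km <- tibble::tibble(
    node_bindings = list(c(disease = "T:d1", gene = "T:g1")),
    edge_bindings = list(list("1" = edge_key(kg$edges)[
      kg$edges$subject == "T:g1" & kg$edges$object == "T:d1"])),
    score = 0.5
  )
  kg_message(qg, kg, km)
}

# Random but internally consistent message, for serialization round-trips
# and mutation testing.
random_message <- function(seed) {
  fed <- random_federation(seed, n_sources = 2, n_concepts = 3,
                           n_nodes = 3, edge_density = 0.6)
  q <- random_path_query(fed, seed + 10000L, n_hops = 2)
  schema <- merge_schema(fetch_transition_maps(fed$registry))
  plan <- plan_query(q, schema, the_model)
  execute_plan(plan, fed$registry, model = the_model)$merged
}

# Canonical one-line fingerprint of an answer set (alias=id pairs per row).
binding_strings <- function(km) {
  sort(vapply(km$node_bindings, function(b) {
    b <- b[order(names(b))]
    paste(names(b), b, sep = "=", collapse = ",")
  }, character(1)))
}

run_use_case <- function(case_id, ...) {
  fed <- build_use_case(case_id)
  list(fed = fed,
       res = run_program(fed$query_text, fed$registry, model = the_model, ...))
}
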