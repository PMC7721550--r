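# Seeded random federations, the brute-force answer oracle, and a random
# program generator — the test harness behind the engine's equivalence and
# round-trip properties.

# Run code under a local RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Mutually incomparable concepts (no ancestor/descendant pairs): with
# single-source concept-pair assignment this makes the planner's service
# choice unique, which the oracle-equivalence property requires.
random_concept_pool <- function() {
  c("gene", "protein", "cell", "anatomical_entity", "disease",
    "phenotypic_feature", "chemical_substance",
    "population_of_individual_organisms", "environmental_feature",
    "biological_process")
}

#' Generate a seeded random federation
#'
#' Draws `n_concepts` mutually incomparable concepts, lays out `n_nodes`
#' nodes per concept, picks a set of concept-pair transitions (consecutive
#' pairs of a random concept chain are always present, so multi-hop queries
#' are plannable, plus random extras), assigns each unordered concept pair
#' to exactly one source, and realizes each transition's node-pair edges
#' with probability `edge_density`. Same seed, same federation — the
#' serialized union graph is byte-identical across calls.
#'
#' @param seed Integer seed.
#' @param n_sources Number of knowledge sources (1-3 typical).
#' @param n_concepts Number of concepts (2..10).
#' @param n_nodes Nodes per concept.
#' @param edge_density Probability an eligible node pair is connected.
#' @param model A [concept_model()].
#' @return A `fixture_federation` with `registry`, `union_kg`, `model`,
#'   `seed`, and the drawn `concept_chain`.
#' @export
random_federation <- function(seed, n_sources = 2, n_concepts = 4,
                              n_nodes = 5, edge_density = 0.3,
                              model = default_concept_model()) {
  stopifnot(n_sources >= 1, n_concepts >= 2, n_nodes >= 1,
            edge_density > 0, edge_density <= 1)
  pool <- random_concept_pool()
  if (n_concepts > length(pool)) {
    abort_argument(paste0("n_concepts must be <= ", length(pool)))
  }
  with_local_seed(seed, {
    concepts <- sample(pool, n_concepts)
    preds <- setdiff(model_predicates(model), model$root_predicate)
    nodes <- purrr::map_dfr(concepts, function(cc) {
      tibble::tibble(
        id = sprintf("R:%s_%02d", cc, seq_len(n_nodes)),
        concept = cc,
        label = sprintf("%s %02d", gsub("_", " ", cc), seq_len(n_nodes))
      )
    })
    # Transitions: the chain pairs plus random extras, predicates drawn
    # uniformly; each unordered concept pair belongs to exactly one source.
    chain_pairs <- tibble::tibble(from = concepts[-n_concepts],
                                  to = concepts[-1])
    all_pairs <- expand.grid(from = concepts, to = concepts,
                             stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
    extra <- all_pairs[stats::runif(nrow(all_pairs)) < 0.25, ]
    transitions <- dplyr::distinct(dplyr::bind_rows(chain_pairs, extra))
    transitions$predicate <- sample(preds, nrow(transitions), replace = TRUE)
    pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
    pairs <- unique(pair_key(transitions$from, transitions$to))
    source_names <- sprintf("src%02d", seq_len(n_sources))
    pair_source <- stats::setNames(
      sample(source_names, length(pairs), replace = TRUE), pairs)
    transitions$service <- unname(
      pair_source[pair_key(transitions$from, transitions$to)])

    # Sample node pairs by index rather than enumerating the full grid, so
    # large sparse federations stay cheap; density 1 yields the complete
    # bipartite edge set.
    edges <- purrr::map_dfr(seq_len(nrow(transitions)), function(i) {
      tr <- transitions[i, ]
      from_ids <- nodes$id[nodes$concept == tr$from]
      to_ids <- nodes$id[nodes$concept == tr$to]
      total <- length(from_ids) * length(to_ids)
      k <- if (edge_density >= 1) total else
        max(1L, stats::rbinom(1, total, edge_density))
      idx <- sample.int(total, k)
      tibble::tibble(
        subject = from_ids[(idx - 1L) %% length(from_ids) + 1L],
        object = to_ids[(idx - 1L) %/% length(from_ids) + 1L],
        predicate = tr$predicate,
        weight = round(stats::runif(k), 3),
        source = tr$service)
    })

    sources <- lapply(source_names, function(sv) {
      sv_edges <- edges[edges$source == sv, , drop = FALSE]
      sv_concepts <- unique(c(transitions$from[transitions$service == sv],
                              transitions$to[transitions$service == sv]))
      sv_nodes <- nodes[nodes$concept %in% sv_concepts, ]
      if (nrow(sv_nodes) == 0) return(NULL)
      fixture_source(sv, knowledge_graph(sv_nodes, sv_edges), model)
    })
    sources <- purrr::compact(sources)
    registry <- source_registry(sources)
    structure(
      list(
        registry = registry,
        union_kg = union_kgs(purrr::map(registry$sources, "kg")),
        truth = NULL,
        query_text = NA_character_,
        model = model,
        seed = as.integer(seed),
        concept_chain = concepts
      ),
      class = "fixture_federation"
    )
  })
}

#' Build a compiled query from a concept path
#'
#' Programmatic counterpart of a `select` statement with unlabeled hops:
#' handy for generated queries and scripting.
#'
#' @param concepts Character vector: the concept path.
#' @param model A [concept_model()].
#' @param service Service reference (default: plan against the schema).
#' @param pinned Optional named list alias -> pinned CURIEs.
#' @return A `compiled_query`.
#' @export
path_query <- function(concepts, model = default_concept_model(),
                       service = "/schema", pinned = list()) {
  aliases <- character(length(concepts))
  for (k in seq_along(concepts)) {
    cnt <- sum(concepts[seq_len(k)] == concepts[k])
    aliases[k] <- if (cnt == 1) concepts[k] else paste0(concepts[k], "_", cnt)
  }
  qg <- query_graph(
    nodes = tibble::tibble(
      alias = aliases, concept = concepts,
      pinned_ids = purrr::map(aliases, function(a) pinned[[a]])),
    edges = if (length(concepts) > 1) tibble::tibble(
      from_alias = aliases[-length(aliases)], to_alias = aliases[-1],
      predicate = NA_character_) else NULL
  )
  structure(
    list(query_graph = qg, service = service,
         options = tibble::tibble(service = character(), name = character(),
                                  value = list()),
         filters = list(), statement = NULL),
    class = "compiled_query"
  )
}

#' Draw a random linear query answerable by a federation's schema
#'
#' Walks the federated schema's transition graph (either direction) for
#' `n_hops` steps starting from a random transition.
#'
#' @param federation A [random_federation()] result.
#' @param seed Integer seed.
#' @param n_hops Number of hops (path length - 1).
#' @return A `compiled_query` with unlabeled hops.
#' @export
random_path_query <- function(federation, seed, n_hops = 2) {
  schema <- merge_schema(fetch_transition_maps(federation$registry))
  tr <- schema$transitions
  if (nrow(tr) == 0) abort_argument("federation has no transitions")
  with_local_seed(seed, {
    # Adjacency over concepts, ignoring direction.
    adj <- dplyr::bind_rows(
      tibble::tibble(a = tr$source_concept, b = tr$target_concept),
      tibble::tibble(a = tr$target_concept, b = tr$source_concept))
    adj <- dplyr::distinct(adj)
    start <- sample(unique(adj$a), 1)
    path <- start
    for (k in seq_len(n_hops)) {
      nxt <- adj$b[adj$a == path[length(path)]]
      if (!length(nxt)) break
      path <- c(path, sample(nxt, 1))
    }
    path_query(path, federation$model)
  })
}

#' Brute-force answer oracle
#'
#' Exhaustively enumerates every node sequence in a knowledge graph that
#' instantiates a linear query path: bidirectional concept-subtype match at
#' each node, predicate-subtype (or wildcard) match at each hop, edges
#' traversable in either direction, pinned identifiers respected. This is
#' the reference semantics the planned, federated, stitched execution is
#' tested against; it is implemented as an independent recursive search,
#' not via the engine's join machinery.
#'
#' @param query A `compiled_query` or [query_graph()].
#' @param union_kg The complete [knowledge_graph()] across all sources.
#' @param model A [concept_model()].
#' @return Tibble with a `node_bindings` list-column (canonical row order).
#' @export
oracle_answers <- function(query, union_kg, model = default_concept_model()) {
  qg <- if (inherits(query, "compiled_query")) query$query_graph else query
  n <- nrow(qg$nodes)
  if (n == 0 || nrow(union_kg$nodes) == 0) {
    return(tibble::tibble(node_bindings = list()))
  }
  concept_of <- stats::setNames(union_kg$nodes$concept, union_kg$nodes$id)
  matches_node <- function(id, k) {
    pins <- qg$nodes$pinned_ids[[k]]
    if (!is.null(pins) && !id %in% pins) return(FALSE)
    any(concept_compatible(model, concept_of[[id]], qg$nodes$concept[k]))
  }
  e <- union_kg$edges
  rows <- list()
  recurse <- function(binding, k) {
    if (k > n) {
      rows[[length(rows) + 1L]] <<- stats::setNames(binding, qg$nodes$alias)
      return(invisible(NULL))
    }
    last <- binding[length(binding)]
    pred <- qg$edges$predicate[k - 1L]
    nbr <- character()
    for (i in seq_len(nrow(e))) {
      if (!predicate_compatible(model, pred, e$predicate[i])) next
      if (e$subject[i] == last) nbr <- c(nbr, e$object[i])
      if (e$object[i] == last) nbr <- c(nbr, e$subject[i])
    }
    for (id in unique(nbr)) {
      if (matches_node(id, k)) recurse(c(binding, id), k + 1L)
    }
  }
  for (id in union_kg$nodes$id) {
    if (matches_node(id, 1L)) recurse(id, 2L)
  }
  km <- normalize_knowledge_map(
    if (length(rows)) tibble::tibble(node_bindings = rows) else NULL)
  km[, "node_bindings", drop = FALSE]
}

# ---- random program generator (parser round-trip fuel) ----------------------

#' Generate a random query-language program
#'
#' Draws a random AST (set / select / create-graph statements, random paths,
#' aliases, predicates, constraints, embedded sets) whose variable
#' references respect assignment order. Used for the pretty-print/parse
#' round-trip property.
#'
#' @param seed Integer seed.
#' @param max_statements Upper bound on statement count.
#' @return A `ql_program`.
#' @export
random_program <- function(seed, max_statements = 4) {
  with_local_seed(seed, {
    rand_ident <- function() {
      repeat {
        w <- paste0(sample(letters, 1),
                    paste(sample(c(letters, as.character(0:9), "_"),
                                 sample(0:6, 1), replace = TRUE), collapse = ""))
        if (!w %in% QL_KEYWORDS) return(w)
      }
    }
    rand_string <- function() {
      paste(sample(c(letters, LETTERS, as.character(0:9), ":", "/", "_", ".",
                     " ", "-"), sample(1:12, 1), replace = TRUE),
            collapse = "")
    }
    rand_number_text <- function() {
      if (stats::runif(1) < 0.5) as.character(sample(0:999, 1))
      else sprintf("%d.%d", sample(0:99, 1), sample(1:99, 1))
    }
    vars <- character()
    kg_vars <- character()
    rand_value <- function() {
      r <- stats::runif(1)
      if (r < 0.45) ql_value("string", rand_string())
      else if (r < 0.9 || !length(vars)) ql_value("number", rand_number_text())
      else ql_value("var", sample(vars, 1))
    }
    rand_set <- function() {
      v <- rand_ident()
      node <- structure(list(variable = v, value = rand_value()),
                        class = "ql_set")
      vars <<- union(vars, v)
      node
    }
    rand_select <- function() {
      n_nodes <- sample(1:4, 1)
      used_aliases <- character()
      path <- purrr::map(seq_len(n_nodes), function(i) {
        alias <- if (stats::runif(1) < 0.4) {
          a <- rand_ident()
          while (a %in% used_aliases) a <- rand_ident()
          used_aliases <<- c(used_aliases, a)
          a
        } else NULL
        list(concept = rand_ident(), alias = alias)
      })
      hops <- purrr::map(seq_len(max(0, n_nodes - 1)), function(i) {
        if (stats::runif(1) < 0.5) rand_ident() else NULL
      })
      constraints <- purrr::map(seq_len(sample(0:3, 1)), function(i) {
        lhs <- if (stats::runif(1) < 0.4)
          c(rand_ident(), rand_ident()) else rand_ident()
        structure(list(lhs = lhs,
                       op = sample(c("=", "<", ">", "<=", ">=", "!="), 1),
                       rhs = rand_value()),
                  class = "ql_constraint")
      })
      embedded <- NULL
      if (stats::runif(1) < 0.4) {
        v <- rand_ident()
        embedded <- list(
          jsonpath = if (stats::runif(1) < 0.5)
            "$.knowledge_graph.nodes[*].id" else NULL,
          variable = v)
        vars <<- union(vars, v)
        if (is.null(embedded$jsonpath)) kg_vars <<- union(kg_vars, v)
      }
      structure(list(path = path, hops = hops,
                     service = paste0("/", rand_ident()),
                     constraints = constraints, embedded_set = embedded),
                class = "ql_select")
    }
    rand_create <- function() {
      structure(list(name = rand_ident(), at = paste0("/", rand_ident()),
                     from_variable = sample(kg_vars, 1)),
                class = "ql_create_graph")
    }
    n <- sample(1:max_statements, 1)
    statements <- purrr::map(seq_len(n), function(i) {
      r <- stats::runif(1)
      if (r < 0.35) rand_set()
      else if (r < 0.9 || !length(kg_vars)) rand_select()
      else rand_create()
    })
    structure(list(statements = statements), class = "ql_program")
  })
}
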