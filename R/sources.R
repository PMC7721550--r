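#' Knowledge-source contract
#'
#' The backplane normalizes every knowledge service behind one contract: a
#' `name`, a `capabilities` [transition_map()], and an `invoke` function
#' taking a query-graph fragment plus service options and returning a
#' [kg_message()]. Responses must bind every fragment alias, connect only
#' returned nodes, and stamp every edge with this source's name — violations
#' are quarantined by [invoke_source()].
#'
#' @param name Service name.
#' @param capabilities A [transition_map()].
#' @param invoke `function(fragment_query_graph, options) -> kg_message`.
#' @return A `knowledge_source`.
#' @export
knowledge_source <- function(name, capabilities, invoke, ...) {
  structure(
    list(name = name, capabilities = capabilities, invoke = invoke,
         calls = new.env(parent = emptyenv()), ...),
    class = "knowledge_source"
  )
}

#' @export
print.knowledge_source <- function(x, ...) {
  cat("<knowledge_source> ", x$name, " (",
      nrow(x$capabilities$transitions), " transitions, ",
      source_invocations(x), " invocations)\n", sep = "")
  invisible(x)
}

source_invocations <- function(source) source$calls$n %||% 0L

count_invocation <- function(source) {
  source$calls$n <- (source$calls$n %||% 0L) + 1L
  invisible(source)
}

# ---- fixture (in-process) sources -------------------------------------------

# Transition types actually present in a shard: the honest capability map.
shard_capabilities <- function(name, kg, model) {
  if (nrow(kg$edges) == 0) {
    return(transition_map(name, tibble::tibble(
      source_concept = character(), target_concept = character(),
      predicate = character()), model))
  }
  concept_of <- stats::setNames(kg$nodes$concept, kg$nodes$id)
  transition_map(name, tibble::tibble(
    source_concept = unname(concept_of[kg$edges$subject]),
    target_concept = unname(concept_of[kg$edges$object]),
    predicate = kg$edges$predicate
  ), model)
}

#' In-process fixture knowledge source
#'
#' Serves a fixed knowledge-graph shard. Its capability map is derived from
#' the shard itself (exactly the transition types present), and `invoke`
#' answers fragments by matching the fragment path against the shard:
#' concept compatibility is bidirectional subtype match, edges are
#' traversable in either direction, pinned identifiers restrict the matched
#' nodes. Every returned edge is stamped with this source's name.
#'
#' @param name Service name.
#' @param kg The shard [knowledge_graph()].
#' @param model A [concept_model()].
#' @return A `knowledge_source`.
#' @export
fixture_source <- function(name, kg, model) {
  kg$edges$source <- name
  kg$nodes$sources <- rep(list(name), nrow(kg$nodes))
  kg <- knowledge_graph(kg$nodes, kg$edges)
  knowledge_source(
    name = name,
    capabilities = shard_capabilities(name, kg, model),
    invoke = function(fragment, options = list()) {
      match_fragment(kg, fragment, model)
    },
    kg = kg
  )
}

# Enumerate all bindings of a linear fragment in a shard via iterative joins.
# (The brute-force oracle in oracle_answers() is a separate, recursive
# implementation; keep these independent.)
match_fragment <- function(kg, qg, model) {
  n <- nrow(qg$nodes)
  cand <- purrr::map(seq_len(n), function(k) {
    ids <- kg$nodes$id[concept_compatible(model, kg$nodes$concept,
                                          qg$nodes$concept[k])]
    pins <- qg$nodes$pinned_ids[[k]]
    if (!is.null(pins)) ids <- intersect(ids, pins)
    ids
  })
  if (any(lengths(cand) == 0)) {
    return(kg_message(qg, empty_kg(), NULL))
  }
  aliases <- qg$nodes$alias
  rows <- tibble::tibble(!!aliases[1] := cand[[1]])
  hop_tables <- list()
  for (k in seq_len(max(0L, n - 1L))) {
    e <- kg$edges
    pred_ok <- vapply(e$predicate, function(p)
      predicate_compatible(model, qg$edges$predicate[k], p), logical(1))
    e <- e[pred_ok, ]
    key <- edge_key(e)
    fwd <- tibble::tibble(from = e$subject, to = e$object, key = key)
    rev <- tibble::tibble(from = e$object, to = e$subject, key = key)
    hop <- dplyr::distinct(dplyr::bind_rows(fwd, rev))
    hop <- hop[hop$from %in% cand[[k]] & hop$to %in% cand[[k + 1]], ]
    hop_tables[[k]] <- hop
    pairs <- dplyr::distinct(hop[, c("from", "to")])
    names(pairs) <- c(aliases[k], aliases[k + 1])
    rows <- dplyr::inner_join(rows, pairs, by = aliases[k],
                              relationship = "many-to-many")
    if (nrow(rows) == 0) break
  }
  if (n > 1 && nrow(rows) == 0) {
    return(kg_message(qg, empty_kg(), NULL))
  }
  rows <- dplyr::distinct(rows)
  used_ids <- unique(unlist(rows))
  row_mat <- as.matrix(rows[, aliases, drop = FALSE])
  dimnames(row_mat) <- list(NULL, aliases)
  node_bindings <- asplit(row_mat, 1)
  # Pre-index hop edges by (from, to); per-row lookup is a vectorized match.
  hop_binding <- purrr::map(seq_len(max(0L, n - 1L)), function(k) {
    hop <- hop_tables[[k]]
    idx <- split(hop$key, paste(hop$from, hop$to, sep = "\r"))
    idx <- lapply(idx, function(ks) sort(unique(ks)))
    pos <- match(paste(row_mat[, k], row_mat[, k + 1L], sep = "\r"),
                 names(idx))
    unname(idx[pos])
  })
  edge_bindings <- purrr::map(seq_len(nrow(rows)), function(i) {
    eb <- purrr::map(hop_binding, function(hb) hb[[i]])
    names(eb) <- as.character(seq_along(hop_binding))
    eb
  })
  used_keys <- unique(unlist(edge_bindings))
  sub_nodes <- kg$nodes[kg$nodes$id %in% used_ids, ]
  sub_edges <- kg$edges[edge_key(kg$edges) %in% used_keys, ]
  kg_message(
    qg,
    knowledge_graph(sub_nodes, sub_edges),
    tibble::tibble(node_bindings = node_bindings,
                   edge_bindings = edge_bindings,
                   score = NA_real_)
  )
}

# ---- registry ---------------------------------------------------------------

#' Registry of knowledge sources
#'
#' @param sources List of [knowledge_source()] objects.
#' @return A `source_registry` keyed by service name.
#' @export
source_registry <- function(sources = list()) {
  names(sources) <- purrr::map_chr(sources, "name")
  if ("/schema" %in% names(sources)) {
    abort_registry("'/schema' is reserved and may not be registered")
  }
  structure(list(sources = sources), class = "source_registry")
}

registry_get <- function(registry, name) {
  src <- registry$sources[[name]]
  if (is.null(src)) abort_registry(paste0("service not registered: ", name))
  src
}

#' Per-source invocation counts
#'
#' @param registry A [source_registry()].
#' @return Named integer vector of invoke() call counts.
#' @export
invocation_counts <- function(registry) {
  purrr::map_int(registry$sources, source_invocations)
}

#' @export
print.source_registry <- function(x, ...) {
  cat("<source_registry> ", paste(names(x$sources), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Load a source registry from a YAML config
#'
#' The config maps service name to `{kind: fixture|http, ...}`. Fixture
#' entries name a packaged federation (`case: 1` or `case: 2`) and the shard
#' to take from it; http entries give an `endpoint` for the live adapter.
#'
#' @param path YAML config path.
#' @param model A [concept_model()].
#' @return A `source_registry`.
#' @export
read_registry <- function(path, model = default_concept_model()) {
  cfg <- yaml::read_yaml(path)
  fixture_cache <- list()
  sources <- list()
  for (name in names(cfg$sources)) {
    entry <- cfg$sources[[name]]
    kind <- entry$kind %||% "fixture"
    src <- if (kind == "fixture") {
      key <- as.character(entry$case)
      if (is.null(fixture_cache[[key]])) {
        fixture_cache[[key]] <- build_use_case(entry$case, model = model)
      }
      found <- fixture_cache[[key]]$registry$sources[[entry$shard %||% name]]
      if (is.null(found)) {
        abort_registry(paste0("fixture case ", entry$case, " has no shard '",
                              entry$shard %||% name, "'"))
      }
      found
    } else if (kind == "http") {
      http_source(name, entry$endpoint)
    } else {
      abort_registry(paste0("unknown source kind: ", kind))
    }
    sources <- c(sources, list(src))
  }
  source_registry(sources)
}

# ---- live HTTP adapter ------------------------------------------------------

#' HTTP knowledge-source adapter
#'
#' Speaks the package's JSON message dialect over POST (`<endpoint>/query`)
#' and fetches the transition map from `<endpoint>/schema`, using the system
#' `curl` binary. This is the live-federation adapter; the packaged test
#' federations use [fixture_source()] instead, so no network is required to
#' run the engine or its tests.
#'
#' @param name Service name.
#' @param endpoint Base URL.
#' @param model A [concept_model()] used to validate the fetched map.
#' @return A `knowledge_source`.
#' @export
http_source <- function(name, endpoint, model = default_concept_model()) {
  fetch <- function(url, payload = NULL) {
    args <- c("-sf", if (!is.null(payload))
      c("-X", "POST", "-H", "Content-Type: application/json",
        "--data-binary", "@-"), url)
    out <- suppressWarnings(system2("curl", args, input = payload,
                                    stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
      abort_registry(paste0("source '", name, "' unreachable at ", url))
    }
    paste(out, collapse = "\n")
  }
  caps_doc <- jsonlite::fromJSON(fetch(paste0(endpoint, "/schema")),
                                 simplifyVector = TRUE)
  caps <- transition_map(name, tibble::as_tibble(caps_doc), model)
  knowledge_source(
    name = name,
    capabilities = caps,
    invoke = function(fragment, options = list()) {
      req <- write_message(kg_message(fragment, NULL, NULL))
      read_message(fetch(paste0(endpoint, "/query"), payload = req))
    }
  )
}
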