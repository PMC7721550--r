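#' Knowledge graph container
#'
#' A knowledge graph is a pair of tibbles: `nodes` (one row per entity, keyed
#' by an opaque CURIE `id`) and `edges` (directed subject -> object
#' assertions). Provenance is first-class: every node carries the set of
#' knowledge sources that asserted it (`sources`, a list-column), and every
#' edge carries the single `source` that returned it. Edge `weight` is a real
#' in \[0, 1\] or `NA` when the source supplied none.
#'
#' Construction canonicalizes the graph: nodes sorted by id, edges sorted by
#' (subject, predicate, object, source), so two graphs with equal content are
#' `identical()` and serialize byte-identically.
#'
#' @param nodes Tibble/data frame with columns `id`, `concept`, and optional
#'   `label`, `attributes` (list), `sources` (list of character).
#' @param edges Tibble/data frame with columns `subject`, `object`,
#'   `predicate`, and optional `weight`, `source`, `attributes`.
#' @param validate Check referential closure and weight ranges.
#' @return A `knowledge_graph` object.
#' @export
knowledge_graph <- function(nodes = NULL, edges = NULL, validate = TRUE) {
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges)
  kg <- structure(list(nodes = nodes, edges = edges), class = "knowledge_graph")
  if (validate) validate_kg(kg)
  kg
}

empty_attr_col <- function(n) rep(list(stats::setNames(list(), character())), n)

normalize_nodes <- function(nodes) {
  if (is.null(nodes) || nrow(tibble::as_tibble(nodes)) == 0) {
    return(tibble::tibble(id = character(), concept = character(),
                          label = character(), attributes = list(),
                          sources = list()))
  }
  nodes <- tibble::as_tibble(nodes)
  n <- nrow(nodes)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label <- ifelse(is.na(nodes$label), nodes$id, nodes$label)
  if (!"attributes" %in% names(nodes)) nodes$attributes <- empty_attr_col(n)
  if (!"sources" %in% names(nodes)) nodes$sources <- rep(list(character()), n)
  nodes$sources <- purrr::map(nodes$sources, function(s) sort(unique(as.character(s))))
  nodes <- nodes[order(nodes$id), c("id", "concept", "label", "attributes", "sources")]
  tibble::as_tibble(nodes)
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0) {
    return(tibble::tibble(subject = character(), object = character(),
                          predicate = character(), weight = numeric(),
                          source = character(), attributes = list()))
  }
  edges <- tibble::as_tibble(edges)
  n <- nrow(edges)
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  if (!"source" %in% names(edges)) edges$source <- NA_character_
  if (!"attributes" %in% names(edges)) edges$attributes <- empty_attr_col(n)
  edges$weight <- as.numeric(edges$weight)
  ord <- order(edges$subject, edges$predicate, edges$object, edges$source,
               edges$weight, method = "radix")
  edges <- edges[ord, c("subject", "object", "predicate", "weight", "source",
                        "attributes")]
  tibble::as_tibble(edges)
}

validate_kg <- function(kg, model = NULL) {
  if (anyDuplicated(kg$nodes$id)) {
    abort_integrity(paste0("duplicate node id: ",
                           kg$nodes$id[duplicated(kg$nodes$id)][1]))
  }
  if (any(!nzchar(kg$nodes$id))) abort_integrity("empty node id")
  dangling <- setdiff(c(kg$edges$subject, kg$edges$object), kg$nodes$id)
  if (length(dangling)) {
    bad <- kg$edges[kg$edges$subject %in% dangling | kg$edges$object %in% dangling, ][1, ]
    abort_integrity(paste0("edge ", bad$subject, " -[", bad$predicate, "]-> ",
                           bad$object, " references a node absent from the graph"))
  }
  w <- kg$edges$weight
  if (any(!is.na(w) & (w < 0 | w > 1))) {
    abort_integrity("edge weight outside [0, 1]")
  }
  if (!is.null(model)) {
    bad <- setdiff(unique(kg$nodes$concept), model_concepts(model))
    if (length(bad)) abort_integrity(paste0("unknown concept in graph: ", bad[1]))
  }
  invisible(kg)
}

empty_kg <- function() knowledge_graph(NULL, NULL, validate = FALSE)

# Canonical edge identity: used for dedup and for answer edge bindings.
edge_key <- function(edges) {
  paste(edges$subject, edges$predicate, edges$object, edges$source, sep = "|")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("<knowledge_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Node connectivity
#'
#' Number of edges incident to a node, ignoring direction; a self-loop
#' counts twice (once per endpoint).
#'
#' @param kg A `knowledge_graph`.
#' @param node_id CURIE of the node (vectorized).
#' @return Integer vector of degrees.
#' @export
kg_degree <- function(kg, node_id) {
  unknown <- setdiff(node_id, kg$nodes$id)
  if (length(unknown)) abort_lookup(paste0("unknown node: ", unknown[1]))
  ends <- c(kg$edges$subject, kg$edges$object)
  counts <- table(ends)
  out <- as.integer(counts[node_id])
  out[is.na(out)] <- 0L
  out
}

all_degrees <- function(kg) {
  stats::setNames(kg_degree(kg, kg$nodes$id), kg$nodes$id)
}

#' Query graph: the template a linear query compiles to
#'
#' Nodes are concept-typed template slots with unique aliases and optional
#' pinned identifiers (from constraints or from an upstream execution
#' segment); edges join consecutive nodes with an optional predicate (`NA` =
#' any). The engine restricts query graphs to a single linear path: edge k
#' connects node k to node k+1.
#'
#' @param nodes Tibble with columns `alias`, `concept`, optional `pinned_ids`
#'   (list of character).
#' @param edges Tibble with columns `from_alias`, `to_alias`, optional
#'   `predicate`.
#' @return A `query_graph`.
#' @export
query_graph <- function(nodes = NULL, edges = NULL) {
  if (is.null(nodes)) {
    nodes <- tibble::tibble(alias = character(), concept = character())
  }
  nodes <- tibble::as_tibble(nodes)
  if (!"pinned_ids" %in% names(nodes)) nodes$pinned_ids <- rep(list(NULL), nrow(nodes))
  nodes <- nodes[, c("alias", "concept", "pinned_ids")]
  if (is.null(edges) || nrow(tibble::as_tibble(edges)) == 0) {
    edges <- tibble::tibble(from_alias = character(), to_alias = character(),
                            predicate = character())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"predicate" %in% names(edges)) edges$predicate <- NA_character_
    edges <- edges[, c("from_alias", "to_alias", "predicate")]
  }
  qg <- structure(list(nodes = nodes, edges = edges), class = "query_graph")
  validate_query_graph(qg)
  qg
}

validate_query_graph <- function(qg) {
  n <- nrow(qg$nodes)
  if (n == 0) {  # degenerate: the empty message envelope
    if (nrow(qg$edges) > 0) abort_integrity("edges without query nodes")
    return(invisible(qg))
  }
  if (anyDuplicated(qg$nodes$alias)) {
    abort_integrity(paste0("duplicate alias: ",
                           qg$nodes$alias[duplicated(qg$nodes$alias)][1]))
  }
  if (!all(grepl("^[a-z_][a-z0-9_]*$", qg$nodes$alias))) {
    abort_integrity("alias must be a lower_snake_case identifier")
  }
  if (nrow(qg$edges) != n - 1L) {
    abort_integrity("query graph must be a single linear path")
  }
  if (n > 1L && (!all(qg$edges$from_alias == qg$nodes$alias[-n]) ||
                 !all(qg$edges$to_alias == qg$nodes$alias[-1]))) {
    abort_integrity("query graph edges must chain consecutive nodes (linear path)")
  }
  invisible(qg)
}

#' @export
print.query_graph <- function(x, ...) {
  hops <- x$nodes$alias[1]
  if (nrow(x$edges) > 0) {
    for (i in seq_len(nrow(x$edges))) {
      p <- x$edges$predicate[i]
      arrow <- if (is.na(p)) "->" else paste0("-[", p, "]->")
      hops <- paste0(hops, arrow, x$nodes$alias[i + 1])
    }
  }
  cat("<query_graph> ", hops, "\n", sep = "")
  invisible(x)
}

# Contiguous slice of a query path covering node indices from..to (inclusive).
qg_slice <- function(qg, from, to) {
  nodes <- qg$nodes[from:to, ]
  edges <- if (to > from) qg$edges[from:(to - 1L), ] else NULL
  query_graph(nodes, edges)
}
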