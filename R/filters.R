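#' Post-query filter settings
#'
#' The three structural views over a merged answer graph: an edge-weight
#' range (edges whose weight falls outside are removed; an absent weight
#' passes as 1.0, so unweighted curated assertions survive default
#' settings), a node-connectivity range (degree computed on the pre-filter
#' graph), and a knowledge-source allow-list (empty set = all sources).
#'
#' @param edge_weight_range Numeric `c(lo, hi)` within \[0, 1\].
#' @param connectivity_range Integer `c(lo, hi)`, `hi` may be `Inf`.
#' @param allowed_sources Character vector of service names; empty keeps all.
#' @return A `filter_settings` object.
#' @export
filter_settings <- function(edge_weight_range = c(0, 1),
                            connectivity_range = c(0, Inf),
                            allowed_sources = character()) {
  if (length(edge_weight_range) != 2 || anyNA(edge_weight_range) ||
      edge_weight_range[1] > edge_weight_range[2] ||
      edge_weight_range[1] < 0 || edge_weight_range[2] > 1) {
    abort_settings("edge_weight_range must be lo <= hi within [0, 1]")
  }
  if (length(connectivity_range) != 2 || anyNA(connectivity_range) ||
      connectivity_range[1] > connectivity_range[2] ||
      connectivity_range[1] < 0) {
    abort_settings("connectivity_range must be 0 <= lo <= hi")
  }
  structure(
    list(edge_weight_range = as.numeric(edge_weight_range),
         connectivity_range = as.numeric(connectivity_range),
         allowed_sources = sort(unique(as.character(allowed_sources)))),
    class = "filter_settings"
  )
}

#' Apply the structural filters to a message
#'
#' Application order is weight, then connectivity, then source. Connectivity
#' is evaluated on the pre-filter graph, so the two structural filters
#' commute in their read phase. Nodes removed by the connectivity filter
#' take their incident edges with them; answer rows referencing any removed
#' node or edge are dropped (rows stay verifiable against the graph). The
#' result always passes message validation.
#'
#' @param message A [kg_message()].
#' @param settings A [filter_settings()].
#' @return The filtered [kg_message()].
#' @export
apply_filters <- function(message, settings = filter_settings()) {
  if (!inherits(settings, "filter_settings")) {
    abort_settings("settings must be a filter_settings object")
  }
  kg <- message$knowledge_graph
  pre_degree <- if (nrow(kg$nodes)) all_degrees(kg) else integer()

  edges <- kg$edges
  w <- ifelse(is.na(edges$weight), 1.0, edges$weight)
  edges <- edges[w >= settings$edge_weight_range[1] &
                   w <= settings$edge_weight_range[2], ]

  keep_node <- pre_degree >= settings$connectivity_range[1] &
    pre_degree <= settings$connectivity_range[2]
  nodes <- kg$nodes[keep_node[kg$nodes$id], ]
  edges <- edges[edges$subject %in% nodes$id & edges$object %in% nodes$id, ]

  if (length(settings$allowed_sources)) {
    edges <- edges[edges$source %in% settings$allowed_sources, ]
  }

  kept_kg <- knowledge_graph(nodes, edges)
  kept_ids <- kept_kg$nodes$id
  kept_keys <- edge_key(kept_kg$edges)
  km <- message$knowledge_map
  if (nrow(km)) {
    nb_flat <- unlist(km$node_bindings, use.names = FALSE)
    nb_grp <- rep.int(seq_len(nrow(km)), lengths(km$node_bindings))
    bad_nb <- unique(nb_grp[!nb_flat %in% kept_ids])
    eb_lens <- vapply(km$edge_bindings, function(e)
      length(unlist(e, use.names = FALSE)), integer(1))
    eb_flat <- unlist(km$edge_bindings, use.names = FALSE)
    eb_grp <- rep.int(seq_len(nrow(km)), eb_lens)
    bad_eb <- unique(eb_grp[!eb_flat %in% kept_keys])
    keep_row <- !seq_len(nrow(km)) %in% c(bad_nb, bad_eb)
    km <- km[keep_row, ]
  }
  kg_message(message$query_graph, kept_kg, km)
}
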