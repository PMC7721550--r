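#' Tabular answer view
#'
#' One row per answer binding, one column per query alias, cells formatted
#' `label (id)`. Row order is deterministic (sorted by the bound ids), so
#' the table is stable across runs and safe to diff.
#'
#' @param message A [kg_message()].
#' @return A tibble with the query aliases as columns.
#' @export
to_table <- function(message) {
  aliases <- message$query_graph$nodes$alias
  labels <- stats::setNames(message$knowledge_graph$nodes$label,
                            message$knowledge_graph$nodes$id)
  km <- message$knowledge_map
  cols <- purrr::map(aliases, function(a) {
    purrr::map_chr(km$node_bindings, function(b) {
      id <- b[[a]]
      paste0(labels[[id]], " (", id, ")")
    })
  })
  out <- tibble::as_tibble(stats::setNames(cols, aliases))
  if (nrow(out)) out <- out[do.call(order, unname(as.list(out))), ]
  out
}

#' Bound node labels per alias
#'
#' Like [to_table()] but with bare labels — convenient for set comparisons
#' against published entity names.
#'
#' @param message A [kg_message()].
#' @return A tibble of labels, one column per alias.
#' @export
answer_labels <- function(message) {
  aliases <- message$query_graph$nodes$alias
  labels <- stats::setNames(message$knowledge_graph$nodes$label,
                            message$knowledge_graph$nodes$id)
  cols <- purrr::map(aliases, function(a) {
    purrr::map_chr(message$knowledge_map$node_bindings,
                   function(b) labels[[b[[a]]]])
  })
  out <- tibble::as_tibble(stats::setNames(cols, aliases))
  if (nrow(out)) out <- out[do.call(order, unname(as.list(out))), ]
  out
}

#' Export a table as TSV
#'
#' @param message A [kg_message()].
#' @param path Output file path.
#' @return The table, invisibly.
#' @export
write_table_tsv <- function(message, path) {
  tb <- to_table(message)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tb)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a message into one row per answer
#'
#' @param x A [kg_message()].
#' @param ... Unused.
#' @return Tibble: one column per query alias holding the bound node id,
#'   plus `score`.
#' @method tidy kg_message
#' @export
tidy.kg_message <- function(x, ...) {
  aliases <- x$query_graph$nodes$alias
  cols <- purrr::map(aliases, function(a) {
    purrr::map_chr(x$knowledge_map$node_bindings, function(b) b[[a]])
  })
  out <- tibble::as_tibble(stats::setNames(cols, aliases))
  out$score <- x$knowledge_map$score
  out
}

#' One-row summary of a message
#'
#' @param x A [kg_message()].
#' @param ... Unused.
#' @return Tibble with node/edge/answer counts and the number of distinct
#'   provenance sources.
#' @method glance kg_message
#' @export
glance.kg_message <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$knowledge_graph$nodes),
    n_edges = nrow(x$knowledge_graph$edges),
    n_answers = nrow(x$knowledge_map),
    n_sources = length(unique(stats::na.omit(x$knowledge_graph$edges$source)))
  )
}

#' Plot the answer knowledge graph
#'
#' A 2D force-directed layout (igraph Fruchterman–Reingold), nodes colored
#' by concept and edges by originating knowledge source — the non-interactive
#' counterpart of a graph-exploration view.
#'
#' @param object A [kg_message()].
#' @param seed Layout seed, for reproducible figures.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kg_message
#' @export
autoplot.kg_message <- function(object, seed = 1L, ...) {
  kg <- object$knowledge_graph
  if (nrow(kg$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty knowledge graph"))
  }
  g <- igraph::graph_from_data_frame(
    d = kg$edges[, c("subject", "object")],
    vertices = kg$nodes$id, directed = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nd <- dplyr::left_join(kg$nodes, pos, by = "id")
  ed <- kg$edges |>
    dplyr::left_join(pos, by = c(subject = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c(object = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, color = .data$source),
      alpha = 0.6) +
    ggplot2::geom_point(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$concept),
      shape = 21, size = 3) +
    ggplot2::geom_text(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 2.5, vjust = -1) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "source", fill = "concept")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
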