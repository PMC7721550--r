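#' Merge per-segment messages into one provenance-preserving message
#'
#' Node union is keyed by CURIE: labels keep the first non-missing value,
#' source sets are unioned, attributes merge last-writer-wins with earlier
#' conflicting values retained in an `attribute_provenance` audit entry, and
#' the node keeps the most specific of the asserted concepts. Two services
#' asserting incompatible concepts for one id is a merge error. Edges
#' deduplicate on (subject, predicate, object, source), so the same
#' assertion from two services remains two edges — provenance preserved.
#' The merged `knowledge_map` is the stitched cross-segment join from
#' [stitch_answers()].
#'
#' @param segments List of per-segment [kg_message()]s, in plan order.
#' @param full_query The full [query_graph()] of the original query.
#' @param model A [concept_model()] for concept-conflict checks.
#' @return A merged [kg_message()].
#' @export
merge_messages <- function(segments, full_query,
                           model = default_concept_model()) {
  segments <- purrr::keep(segments, function(m) nrow(m$query_graph$nodes) > 0)
  if (length(segments) == 0) {
    return(kg_message(full_query, empty_kg(), NULL))
  }
  nodes <- purrr::map_dfr(segments, function(m) m$knowledge_graph$nodes)
  merged_nodes <- NULL
  if (nrow(nodes) > 0) {
    # Only ids asserted more than once need reconciliation; the rest pass
    # through untouched (keeps merging linear on large graphs).
    dup_ids <- unique(nodes$id[duplicated(nodes$id)])
    is_dup <- nodes$id %in% dup_ids
    singles <- nodes[!is_dup, ]
    groups <- split(which(is_dup), nodes$id[is_dup])
    resolve_group <- function(idx) {
      nid <- nodes$id[idx[1]]
      concept <- nodes$concept[idx[1]]
      for (cc in nodes$concept[idx[-1]]) {
        if (is_subtype(model, cc, concept)) {
          concept <- cc  # more specific assertion wins
        } else if (!is_subtype(model, concept, cc)) {
          srcs <- sort(unique(unlist(nodes$sources[idx])))
          abort_merge(paste0("node ", nid, " asserted with incompatible ",
                             "concepts ", concept, " vs ", cc, " by sources: ",
                             paste(srcs, collapse = ", ")))
        }
      }
      attrs <- stats::setNames(list(), character())
      audit <- character()
      for (i in idx) {
        for (k in names(nodes$attributes[[i]])) {
          v <- nodes$attributes[[i]][[k]]
          old <- attrs[[k]]
          if (!is.null(old) && !identical(old, v)) {
            audit <- c(audit, paste0(k, "=", paste(old, collapse = ",")))
          }
          attrs[[k]] <- v
        }
      }
      if (length(audit)) attrs[["attribute_provenance"]] <- audit
      list(concept = concept, attributes = attrs)
    }
    resolved <- lapply(groups, resolve_group)
    first <- unname(vapply(groups, `[[`, integer(1), 1L))
    reconciled <- tibble::tibble(
      id = nodes$id[first],
      concept = unname(vapply(resolved, `[[`, character(1), "concept")),
      label = nodes$label[first],
      attributes = unname(lapply(resolved, `[[`, "attributes")),
      sources = unname(lapply(groups, function(idx)
        sort(unique(unlist(nodes$sources[idx])))))
    )
    merged_nodes <- dplyr::bind_rows(singles, reconciled)
  }
  edges <- purrr::map_dfr(segments, function(m) m$knowledge_graph$edges)
  if (nrow(edges) > 0) {
    edges <- edges[!duplicated(edge_key(edges)), ]
  }
  kg <- knowledge_graph(merged_nodes, edges)
  km <- stitch_answers(segments, full_query)
  kg_message(full_query, kg, km)
}

#' Stitch per-segment answer rows into full-path answers
#'
#' Relational join of adjacent segments' answer rows on the node identifier
#' bound to their shared join alias; each surviving output row binds every
#' alias of the full query. Rows without a join partner are dropped. Edge
#' bindings are re-indexed from segment-local query-edge positions to
#' full-query positions.
#'
#' @param segments List of per-segment [kg_message()]s, in plan order.
#' @param full_query The full [query_graph()].
#' @return A knowledge-map tibble (`node_bindings`, `edge_bindings`, `score`).
#' @export
stitch_answers <- function(segments, full_query) {
  segments <- purrr::keep(segments, function(m) nrow(m$query_graph$nodes) > 0)
  if (length(segments) == 0) return(NULL)
  seg_rows <- lapply(segments, function(m) {
    offset <- match(m$query_graph$nodes$alias[1], full_query$nodes$alias)
    if (is.na(offset)) {
      abort_merge(paste0("segment alias '", m$query_graph$nodes$alias[1],
                         "' is not part of the full query"))
    }
    purrr::map(seq_len(nrow(m$knowledge_map)), function(i) {
      eb <- m$knowledge_map$edge_bindings[[i]]
      if (length(eb)) {
        names(eb) <- as.character(as.integer(names(eb)) + offset - 1L)
      }
      list(nb = m$knowledge_map$node_bindings[[i]], eb = eb,
           score = m$knowledge_map$score[[i]])
    })
  })
  merge_eb <- function(e1, e2) {
    out <- e1
    for (nm in names(e2)) {
      out[[nm]] <- sort(unique(c(out[[nm]], e2[[nm]])))
    }
    out
  }
  acc <- seg_rows[[1]]
  for (s in seq_along(seg_rows)[-1]) {
    nxt <- seg_rows[[s]]
    join_alias <- segments[[s]]$query_graph$nodes$alias[1]
    by_id <- split(nxt, purrr::map_chr(nxt, function(r) r$nb[[join_alias]]))
    acc <- purrr::list_flatten(purrr::map(acc, function(r) {
      partners <- by_id[[r$nb[[join_alias]]]]
      if (is.null(partners)) return(list())
      # natural join: every alias both sides bind must agree, not just the
      # designated join alias (segments may overlap more widely)
      shared <- NULL
      out <- purrr::map(partners, function(p) {
        if (is.null(shared)) {
          shared <<- intersect(names(r$nb), names(p$nb))
        }
        if (!all(r$nb[shared] == p$nb[shared])) return(NULL)
        nb <- c(r$nb, p$nb[setdiff(names(p$nb), names(r$nb))])
        list(nb = nb[order(names(nb))], eb = merge_eb(r$eb, p$eb),
             score = r$score)
      })
      purrr::compact(out)
    }))
    if (length(acc) == 0) break
  }
  if (length(acc) == 0) return(NULL)
  tibble::tibble(
    node_bindings = purrr::map(acc, "nb"),
    edge_bindings = purrr::map(acc, "eb"),
    score = purrr::map_dbl(acc, "score")
  )
}
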