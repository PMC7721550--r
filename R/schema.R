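#' Per-source semantic transition map
#'
#' A knowledge source advertises its capabilities as transitions: for each
#' (source concept, target concept) pair, the predicates it can answer.
#' These maps are the raw material of query planning.
#'
#' @param service Service name.
#' @param transitions Tibble with columns `source_concept`, `target_concept`,
#'   `predicate`.
#' @param model A [concept_model()] used to validate all names.
#' @return A `transition_map`.
#' @export
transition_map <- function(service, transitions, model) {
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("source_concept", "target_concept", "predicate") %in%
                  names(transitions)))
  for (cc in unique(c(transitions$source_concept, transitions$target_concept))) {
    if (!has_concept(model, cc)) {
      abort_kgql(paste0("source '", service, "' advertises unknown concept: ", cc),
                 "kgql_validation_error")
    }
  }
  for (p in unique(transitions$predicate)) {
    if (!is.na(p) && !has_predicate(model, p)) {
      abort_kgql(paste0("source '", service, "' advertises unknown predicate: ", p),
                 "kgql_validation_error")
    }
  }
  if (any(is.na(transitions$predicate) | !nzchar(transitions$predicate))) {
    abort_kgql(paste0("source '", service, "' has a transition with no predicate"),
               "kgql_validation_error")
  }
  transitions <- dplyr::distinct(
    transitions[, c("source_concept", "target_concept", "predicate")])
  transitions <- dplyr::arrange(transitions, .data$source_concept,
                                .data$target_concept, .data$predicate)
  structure(list(service = service, transitions = transitions),
            class = "transition_map")
}

#' Collect transition maps from every registered source
#'
#' @param registry A [source_registry()].
#' @return List of `transition_map`, one per source.
#' @export
fetch_transition_maps <- function(registry) {
  lapply(registry$sources, function(src) {
    caps <- src$capabilities
    if (is.null(caps)) {
      abort_registry(paste0("source '", src$name, "' returned no transition map"))
    }
    caps
  })
}

#' Merge per-source transition maps into a federated schema
#'
#' The union of all (source concept, target concept, predicate, service)
#' tuples. A transition offered by two services keeps both tuples — the
#' planner chooses between them.
#'
#' @param maps List of [transition_map()].
#' @return A `federated_schema` with a `transitions` tibble and the set of
#'   declared `services`.
#' @export
merge_schema <- function(maps) {
  services <- sort(unique(purrr::map_chr(maps, "service")))
  transitions <- purrr::map_dfr(maps, function(m) {
    dplyr::mutate(m$transitions, service = m$service)
  })
  if (nrow(transitions) == 0) {
    transitions <- tibble::tibble(source_concept = character(),
                                  target_concept = character(),
                                  predicate = character(),
                                  service = character())
  }
  transitions <- dplyr::arrange(
    dplyr::distinct(transitions),
    .data$source_concept, .data$target_concept, .data$predicate, .data$service)
  structure(list(transitions = transitions, services = services),
            class = "federated_schema")
}

#' @export
print.federated_schema <- function(x, ...) {
  cat("<federated_schema> ", length(x$services), " services, ",
      nrow(x$transitions), " transitions\n", sep = "")
  invisible(x)
}

# Services able to serve one query edge. Concept compatibility is
# bidirectional subtype match, the edge may match a transition in either
# orientation, and an unlabeled query predicate matches any predicate.
edge_candidates <- function(schema, model, from_concept, to_concept, predicate) {
  tr <- schema$transitions
  if (nrow(tr) == 0) return(character())
  ok <- vapply(seq_len(nrow(tr)), function(i) {
    fwd <- concept_compatible(model, from_concept, tr$source_concept[i]) &&
      concept_compatible(model, to_concept, tr$target_concept[i])
    rev <- concept_compatible(model, from_concept, tr$target_concept[i]) &&
      concept_compatible(model, to_concept, tr$source_concept[i])
    (fwd || rev) && predicate_compatible(model, predicate, tr$predicate[i])
  }, logical(1))
  sort(unique(tr$service[ok]))
}

#' Plan a compiled query against the federated schema
#'
#' Splits the linear query path into contiguous service-tagged segments.
#' Planning happens only for the reserved service reference `"/schema"`; a
#' concrete service reference yields a single segment against that service
#' directly. Each query edge is matched to candidate services; consecutive
#' edges that can stay on one service are coalesced into one segment
#' (maximal coalescing), with lexicographic service name as the tie-break
#' among new candidates. Each segment after the first records the
#' `join_alias` it shares with the previous segment.
#'
#' @param query A [compile_select()] result.
#' @param schema A [merge_schema()] result.
#' @param model A [concept_model()].
#' @return A `query_plan` (list of segments: `service`, `sub_path`,
#'   `options`, `join_alias`).
#' @export
plan_query <- function(query, schema, model) {
  qg <- query$query_graph
  seg_options <- function(service) {
    opts <- query$options[is.na(query$options$service) |
                            query$options$service == service, ]
    stats::setNames(opts$value, opts$name)
  }
  if (!identical(query$service, "/schema")) {
    service <- sub("^/", "", query$service)
    seg <- list(service = service, sub_path = qg,
                options = seg_options(service), join_alias = NULL)
    return(structure(list(segments = list(seg), query = query),
                     class = "query_plan"))
  }
  n <- nrow(qg$nodes)
  if (n == 1) {
    # Single-node query: any service whose map mentions a compatible concept.
    tr <- schema$transitions
    ok <- vapply(seq_len(nrow(tr)), function(i) {
      any(concept_compatible(model, qg$nodes$concept[1],
                             c(tr$source_concept[i], tr$target_concept[i])))
    }, logical(1))
    cand <- sort(unique(tr$service[ok]))
    if (!length(cand)) {
      abort_plan(paste0("no service can serve concept ", qg$nodes$concept[1]))
    }
    seg <- list(service = cand[1], sub_path = qg,
                options = seg_options(cand[1]), join_alias = NULL)
    return(structure(list(segments = list(seg), query = query),
                     class = "query_plan"))
  }

  cands <- lapply(seq_len(n - 1L), function(i) {
    cc <- edge_candidates(schema, model,
                          qg$nodes$concept[i], qg$nodes$concept[i + 1],
                          qg$edges$predicate[i])
    if (!length(cc)) {
      p <- qg$edges$predicate[i]
      abort_plan(paste0("no service can serve step (", qg$nodes$concept[i],
                        ", ", if (is.na(p)) "any" else p, ", ",
                        qg$nodes$concept[i + 1], ")"))
    }
    cc
  })
  chosen <- character(n - 1L)
  chosen[1] <- cands[[1]][1]
  for (i in seq_len(n - 1L)[-1]) {
    chosen[i] <- if (chosen[i - 1] %in% cands[[i]]) chosen[i - 1] else cands[[i]][1]
  }
  # Coalesce runs of identical services into segments.
  runs <- rle(chosen)
  segments <- list()
  start <- 1L
  prev_end_alias <- NULL
  for (r in seq_along(runs$lengths)) {
    end <- start + runs$lengths[r]  # node index closing this run of edges
    seg <- list(
      service = runs$values[r],
      sub_path = qg_slice(qg, start, end),
      options = seg_options(runs$values[r]),
      join_alias = prev_end_alias
    )
    segments <- c(segments, list(seg))
    prev_end_alias <- qg$nodes$alias[end]
    start <- end
  }
  plan <- structure(list(segments = segments, query = query),
                    class = "query_plan")
  check_plan_coverage(plan, qg)
  plan
}

# Segments must partition the query edges exactly, in order.
check_plan_coverage <- function(plan, qg) {
  covered <- purrr::map_dfr(plan$segments, function(s) s$sub_path$edges)
  if (!identical(tibble::as_tibble(covered), tibble::as_tibble(qg$edges))) {
    abort_plan("internal: plan segments do not partition the query path")
  }
  invisible(plan)
}

#' @export
print.query_plan <- function(x, ...) {
  cat("<query_plan> ", length(x$segments), " segment(s)\n", sep = "")
  for (s in x$segments) {
    cat("  [", s$service, "] ", paste(s$sub_path$nodes$alias, collapse = " -> "),
        if (!is.null(s$join_alias)) paste0("  (join: ", s$join_alias, ")") else "",
        "\n", sep = "")
  }
  invisible(x)
}
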