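#' Message envelope: query graph + knowledge graph + answer bindings
#'
#' The unit of exchange with every knowledge source, modeled on the
#' message pattern of federated biomedical graph APIs: a `query_graph`
#' (the question template), a
#' `knowledge_graph` (the returned assertions), and a `knowledge_map` — one
#' row per answer, binding every query alias to a concrete node id and every
#' query edge (by index) to the edge keys that realize the hop.
#'
#' @param query_graph A [query_graph()].
#' @param knowledge_graph A [knowledge_graph()].
#' @param knowledge_map Tibble with list-columns `node_bindings` (named
#'   character: alias -> node id), `edge_bindings` (named list: query-edge
#'   index as character -> character vector of edge keys) and numeric
#'   `score` (optional, `NA` allowed).
#' @param validate Enforce referential closure and binding completeness.
#' @return A `kg_message`.
#' @export
kg_message <- function(query_graph, knowledge_graph = NULL,
                       knowledge_map = NULL, validate = TRUE) {
  knowledge_graph <- knowledge_graph %||% empty_kg()
  knowledge_map <- normalize_knowledge_map(knowledge_map)
  msg <- structure(
    list(query_graph = query_graph, knowledge_graph = knowledge_graph,
         knowledge_map = knowledge_map),
    class = "kg_message"
  )
  if (validate) validate_message(msg)
  msg
}

normalize_knowledge_map <- function(km) {
  if (is.null(km) || nrow(tibble::as_tibble(km)) == 0) {
    return(tibble::tibble(node_bindings = list(), edge_bindings = list(),
                          score = numeric()))
  }
  km <- tibble::as_tibble(km)
  if (!"edge_bindings" %in% names(km)) {
    km$edge_bindings <- rep(list(stats::setNames(list(), character())), nrow(km))
  }
  if (!"score" %in% names(km)) km$score <- NA_real_
  nb <- lapply(km$node_bindings, function(b) unlist(b))
  # Rows almost always share one alias layout; sort names once in that case.
  nms <- lapply(nb, names)
  if (length(nb) && all(vapply(nms, identical, logical(1), nms[[1]]))) {
    perm <- order(nms[[1]])
    if (!identical(perm, seq_along(perm))) {
      nb <- lapply(nb, function(b) b[perm])
    }
  } else {
    nb <- lapply(nb, function(b) b[order(names(b))])
  }
  km$node_bindings <- nb
  km$edge_bindings <- lapply(km$edge_bindings, function(b) {
    b <- lapply(b, function(v)
      if (length(v) > 1) sort(unique(as.character(v))) else as.character(v))
    if (length(b) > 1 && is.unsorted(names(b))) b[order(names(b))] else b
  })
  km <- km[, c("node_bindings", "edge_bindings", "score")]
  # Canonical form: rows are a set — drop exact duplicates (same bindings,
  # same edge keys) and order by the concatenation of bound ids.
  key <- vapply(nb, paste, character(1), collapse = "\r")
  eb_key <- vapply(km$edge_bindings, function(b)
    paste(names(b), vapply(b, paste, character(1), collapse = ","),
          sep = "=", collapse = ";"), character(1))
  keep <- !duplicated(paste(key, eb_key, km$score, sep = "\r"))
  km <- km[keep, ]
  km[order(key[keep], method = "radix"), ]
}

validate_message <- function(msg) {
  validate_kg(msg$knowledge_graph)
  validate_query_graph(msg$query_graph)
  aliases <- msg$query_graph$nodes$alias
  ids <- msg$knowledge_graph$nodes$id
  ekeys <- edge_key(msg$knowledge_graph$edges)
  n_edges <- nrow(msg$query_graph$edges)
  km <- msg$knowledge_map
  if (nrow(km) == 0) return(invisible(msg))
  bound_names <- unlist(purrr::map(km$node_bindings, names))
  if (length(bound_names) != nrow(km) * length(aliases) ||
      !all(bound_names %in% aliases)) {
    bad <- which(vapply(km$node_bindings, function(b)
      length(setdiff(aliases, names(b))) > 0, logical(1)))[1]
    if (is.na(bad)) abort_integrity("answer row binds an unknown alias")
    abort_integrity(paste0(
      "answer row ", bad, " leaves alias unbound: ",
      setdiff(aliases, names(km$node_bindings[[bad]]))[1]))
  }
  bound_ids <- unlist(km$node_bindings, use.names = FALSE)
  lost <- setdiff(bound_ids, ids)
  if (length(lost)) {
    abort_integrity(paste0("answer row binds missing node: ", lost[1]))
  }
  eb_all <- unlist(km$edge_bindings, use.names = FALSE)
  lostk <- setdiff(eb_all, ekeys)
  if (length(lostk)) {
    abort_integrity(paste0("answer row binds missing edge: ", lostk[1]))
  }
  idx <- suppressWarnings(as.integer(unlist(purrr::map(km$edge_bindings,
                                                       names))))
  if (length(idx) && (anyNA(idx) || any(idx < 1L) ||
                        any(idx > max(n_edges, 0L)))) {
    abort_integrity("answer row binds unknown query edge")
  }
  invisible(msg)
}

#' @export
print.kg_message <- function(x, ...) {
  cat("<kg_message> ", nrow(x$knowledge_graph$nodes), " nodes, ",
      nrow(x$knowledge_graph$edges), " edges, ",
      nrow(x$knowledge_map), " answers\n", sep = "")
  print(x$query_graph)
  invisible(x)
}

# ---- canonical JSON serialization -------------------------------------------
# Keys emitted in fixed alphabetical order; nodes/edges/rows already in
# canonical order from the constructors, so two writes of equal messages are
# byte-identical and read(write(m)) reproduces m exactly.

scalar_or_null <- function(x) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) NULL else jsonlite::unbox(x)
}

attrs_json <- function(a) {
  if (length(a) == 0) return(stats::setNames(list(), character()))
  a <- a[order(names(a))]
  purrr::map(a, function(v) if (length(v) == 1) jsonlite::unbox(v) else v)
}

#' Serialize a message to canonical JSON
#'
#' Deterministic: sorted object keys, canonical node/edge/answer ordering,
#' full numeric precision. `read_message(write_message(m))` reproduces `m`,
#' and two writes of the same message are byte-identical.
#'
#' @param message A `kg_message`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
write_message <- function(message, path = NULL) {
  qg <- message$query_graph
  kg <- message$knowledge_graph
  km <- message$knowledge_map
  body <- list(
    knowledge_graph = list(
      edges = purrr::map(seq_len(nrow(kg$edges)), function(i) {
        e <- kg$edges[i, ]
        out <- list(
          attributes = attrs_json(e$attributes[[1]]),
          object = jsonlite::unbox(e$object),
          predicate = jsonlite::unbox(e$predicate),
          source = scalar_or_null(e$source),
          subject = jsonlite::unbox(e$subject),
          weight = scalar_or_null(e$weight)
        )
        out[!vapply(out, is.null, logical(1))]
      }),
      nodes = purrr::map(seq_len(nrow(kg$nodes)), function(i) {
        nd <- kg$nodes[i, ]
        list(
          attributes = attrs_json(nd$attributes[[1]]),
          concept = jsonlite::unbox(nd$concept),
          id = jsonlite::unbox(nd$id),
          label = jsonlite::unbox(nd$label),
          sources = as.list(nd$sources[[1]])
        )
      })
    ),
    knowledge_map = purrr::map(seq_len(nrow(km)), function(i) {
      out <- list(
        edge_bindings = purrr::map(km$edge_bindings[[i]], as.list),
        node_bindings = purrr::map(as.list(km$node_bindings[[i]]), jsonlite::unbox),
        score = scalar_or_null(km$score[[i]])
      )
      out[!vapply(out, is.null, logical(1))]
    }),
    query_graph = list(
      edges = purrr::map(seq_len(nrow(qg$edges)), function(i) {
        e <- qg$edges[i, ]
        out <- list(
          from_alias = jsonlite::unbox(e$from_alias),
          predicate = scalar_or_null(e$predicate),
          to_alias = jsonlite::unbox(e$to_alias)
        )
        out[!vapply(out, is.null, logical(1))]
      }),
      nodes = purrr::map(seq_len(nrow(qg$nodes)), function(i) {
        nd <- qg$nodes[i, ]
        out <- list(
          alias = jsonlite::unbox(nd$alias),
          concept = jsonlite::unbox(nd$concept),
          pinned_ids = if (is.null(nd$pinned_ids[[1]])) NULL else
            as.list(nd$pinned_ids[[1]])
        )
        out[!vapply(out, is.null, logical(1))]
      })
    )
  )
  txt <- jsonlite::toJSON(body, digits = NA, null = "null", pretty = FALSE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Read a message from canonical JSON
#'
#' @param x JSON text, or a path to a file containing it.
#' @param validate Enforce message invariants after reading.
#' @return A `kg_message`.
#' @export
read_message <- function(x, validate = TRUE) {
  if (length(x) == 1 && !grepl("^\\s*\\{", x) && file.exists(x)) {
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (k in c("query_graph", "knowledge_graph", "knowledge_map")) {
    if (is.null(doc[[k]])) abort_integrity(paste0("message lacks key: ", k))
  }
  attrs_in <- function(a) {
    if (is.null(a) || length(a) == 0) return(stats::setNames(list(), character()))
    purrr::map(a, function(v) if (is.list(v)) unlist(v) else v)
  }
  qn <- doc$query_graph$nodes
  qg <- query_graph(
    nodes = tibble::tibble(
      alias = purrr::map_chr(qn, "alias"),
      concept = purrr::map_chr(qn, "concept"),
      pinned_ids = purrr::map(qn, function(nd)
        if (is.null(nd$pinned_ids)) NULL else unlist(nd$pinned_ids))
    ),
    edges = if (length(doc$query_graph$edges) == 0) NULL else tibble::tibble(
      from_alias = purrr::map_chr(doc$query_graph$edges, "from_alias"),
      to_alias = purrr::map_chr(doc$query_graph$edges, "to_alias"),
      predicate = purrr::map_chr(doc$query_graph$edges,
                                 function(e) e$predicate %||% NA_character_)
    )
  )
  kn <- doc$knowledge_graph$nodes
  ke <- doc$knowledge_graph$edges
  kg <- knowledge_graph(
    nodes = if (length(kn) == 0) NULL else tibble::tibble(
      id = purrr::map_chr(kn, "id"),
      concept = purrr::map_chr(kn, "concept"),
      label = purrr::map_chr(kn, function(nd) nd$label %||% nd$id),
      attributes = purrr::map(kn, function(nd) attrs_in(nd$attributes)),
      sources = purrr::map(kn, function(nd) unlist(nd$sources) %||% character())
    ),
    edges = if (length(ke) == 0) NULL else tibble::tibble(
      subject = purrr::map_chr(ke, "subject"),
      object = purrr::map_chr(ke, "object"),
      predicate = purrr::map_chr(ke, "predicate"),
      weight = purrr::map_dbl(ke, function(e) e$weight %||% NA_real_),
      source = purrr::map_chr(ke, function(e) e$source %||% NA_character_),
      attributes = purrr::map(ke, function(e) attrs_in(e$attributes))
    ),
    validate = FALSE
  )
  km <- if (length(doc$knowledge_map) == 0) NULL else tibble::tibble(
    node_bindings = purrr::map(doc$knowledge_map, function(r) unlist(r$node_bindings)),
    edge_bindings = purrr::map(doc$knowledge_map, function(r)
      purrr::map(r$edge_bindings %||% list(), function(v) unlist(v) %||% character())),
    score = purrr::map_dbl(doc$knowledge_map, function(r) r$score %||% NA_real_)
  )
  kg_message(qg, kg, km, validate = validate)
}
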