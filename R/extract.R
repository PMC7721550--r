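# JSONPath variable extraction and the named-graph store.

# Minimal JSONPath evaluator over parsed JSON (nested R lists). Supported:
#   $            root
#   .name        child member
#   .*  / [*]    wildcard over members/elements
#   [n]          array index (0-based, per JSONPath convention)
#   ['name']     quoted child member
# This is the subset the query language exercises; a match list is always
# returned (possibly empty), never an error for missing members.
jsonpath_tokens <- function(expr) {
  if (!is.character(expr) || length(expr) != 1 || !nzchar(expr) ||
      substr(expr, 1, 1) != "$") {
    abort_expression("JSONPath expression must start with '$'")
  }
  rest <- substring(expr, 2)
  steps <- list()
  while (nzchar(rest)) {
    if (startsWith(rest, ".")) {
      rest <- substring(rest, 2)
      if (startsWith(rest, "*")) {
        steps <- c(steps, list(list(kind = "wild")))
        rest <- substring(rest, 2)
      } else {
        m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
        if (!length(m)) abort_expression(paste0("invalid JSONPath member in: ", expr))
        steps <- c(steps, list(list(kind = "child", name = m)))
        rest <- substring(rest, nchar(m) + 1)
      }
    } else if (startsWith(rest, "[")) {
      close <- regexpr("]", rest, fixed = TRUE)
      if (close < 0) abort_expression(paste0("unclosed '[' in: ", expr))
      inner <- substr(rest, 2, close - 1)
      rest <- substring(rest, close + 1)
      if (inner == "*") {
        steps <- c(steps, list(list(kind = "wild")))
      } else if (grepl("^[0-9]+$", inner)) {
        steps <- c(steps, list(list(kind = "index", i = as.integer(inner) + 1L)))
      } else if (grepl("^'[^']*'$", inner) || grepl('^"[^"]*"$', inner)) {
        steps <- c(steps, list(list(kind = "child",
                                    name = substr(inner, 2, nchar(inner) - 1))))
      } else {
        abort_expression(paste0("invalid JSONPath selector: [", inner, "]"))
      }
    } else {
      abort_expression(paste0("invalid JSONPath syntax near: ", rest))
    }
  }
  steps
}

jsonpath_query <- function(doc, expr) {
  steps <- jsonpath_tokens(expr)
  matches <- list(doc)
  for (step in steps) {
    matches <- purrr::list_flatten(purrr::map(matches, function(m) {
      if (step$kind == "child") {
        if (is.list(m) && !is.null(m[[step$name]])) list(m[[step$name]]) else list()
      } else if (step$kind == "index") {
        if (is.list(m) && length(m) >= step$i) list(m[[step$i]]) else list()
      } else {  # wildcard
        if (is.list(m)) unname(purrr::map(m, identity)) else list()
      }
    }))
  }
  matches
}

#' Extract a value from a message with a JSONPath expression
#'
#' Evaluates the expression against the message's canonical JSON
#' serialization and returns the list of matches (scalars unboxed; no match
#' gives an empty list, not an error). `expr = NULL` is the whole-graph
#' marker: the message's [knowledge_graph()] itself is returned — this is
#' what an embedded `set kg_var` without a path assigns.
#'
#' @param message A [kg_message()].
#' @param expr JSONPath string, or `NULL` for the whole graph.
#' @return List of matched values, or a `knowledge_graph`.
#' @export
extract_variable <- function(message, expr = NULL) {
  if (is.null(expr)) return(message$knowledge_graph)
  doc <- jsonlite::fromJSON(write_message(message), simplifyVector = FALSE)
  jsonpath_query(doc, expr)
}

# ---- named-graph store ------------------------------------------------------

#' Named-graph store
#'
#' Destination of the `create graph <name> at <store> from <var>` statement:
#' keeps knowledge graphs under unique names, in memory and (optionally)
#' backed by a directory holding one canonical message file per name.
#' Storing under an existing name overwrites, with a warning.
#'
#' @param dir Optional backing directory (created if missing).
#' @return A `named_graph_store` (environment-backed; reference semantics).
#' @export
named_graph_store <- function(dir = NULL) {
  env <- new.env(parent = emptyenv())
  env$graphs <- new.env(parent = emptyenv())
  env$dir <- dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(env, class = "named_graph_store")
}

#' Store a knowledge graph under a name
#'
#' @param store A [named_graph_store()].
#' @param name Identifier for the graph.
#' @param kg A [knowledge_graph()].
#' @return The store, invisibly.
#' @export
store_named_graph <- function(store, name, kg) {
  validate_kg(kg)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)) {
    abort_argument(paste0("invalid graph name: ", name))
  }
  if (!is.null(get0(name, envir = store$graphs, ifnotfound = NULL))) {
    rlang::warn(paste0("named graph '", name, "' overwritten"),
                class = "kgql_overwrite_warning")
  }
  assign(name, kg, envir = store$graphs)
  if (!is.null(store$dir)) {
    msg <- kg_message(query_graph(), kg, NULL)
    write_message(msg, file.path(store$dir, paste0(name, ".json")))
  }
  invisible(store)
}

#' Load a named graph back from the store
#'
#' In-memory entries win; otherwise the backing directory is read and the
#' reloaded graph re-validated.
#'
#' @param store A [named_graph_store()].
#' @param name Graph name.
#' @return A `knowledge_graph`.
#' @export
load_named_graph <- function(store, name) {
  kg <- get0(name, envir = store$graphs, ifnotfound = NULL)
  if (!is.null(kg)) return(kg)
  if (!is.null(store$dir)) {
    path <- file.path(store$dir, paste0(name, ".json"))
    if (file.exists(path)) {
      return(read_message(path)$knowledge_graph)
    }
  }
  abort_lookup(paste0("no named graph: ", name))
}

#' Names present in a store
#' @param store A [named_graph_store()].
#' @return Character vector.
#' @export
store_names <- function(store) sort(ls(store$graphs))
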