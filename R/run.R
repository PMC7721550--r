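#' Run a query-language program
#'
#' Executes every statement in order: `set` updates the variable store;
#' `select` compiles the path, plans it against the federated schema (or a
#' directly named service), executes the plan segment by segment with
#' answer propagation, merges the per-segment messages, applies any
#' deferred result filters and the embedded `set` extraction; `create
#' graph` writes a variable's knowledge graph to the named-graph store.
#'
#' @param text Program source text.
#' @param registry A [source_registry()].
#' @param model A [concept_model()].
#' @param cache A [query_cache()] (`NULL` disables caching entirely).
#' @param store A [named_graph_store()].
#' @param settings [filter_settings()] applied to each merged result.
#' @return A `program_result`: `message` (the last merged, filtered
#'   [kg_message()]), `messages` (one per select), `variables`, `store`.
#' @export
run_program <- function(text, registry, model = default_concept_model(),
                        cache = query_cache(), store = named_graph_store(),
                        settings = filter_settings()) {
  program <- parse_program(text)
  schema <- merge_schema(fetch_transition_maps(registry))
  variables <- list()
  results <- list()
  for (stmt in program$statements) {
    if (inherits(stmt, "ql_set")) {
      v <- stmt$value
      variables[[stmt$variable]] <- if (v$type == "var") {
        variables[[v$text]]
      } else {
        value_data(v)
      }
    } else if (inherits(stmt, "ql_select")) {
      compiled <- compile_select(stmt, model, variables,
                                 services = names(registry$sources))
      plan <- plan_query(compiled, schema, model)
      exec <- execute_plan(plan, registry, cache = cache, query_text = text,
                           model = model)
      msg <- apply_result_filters(exec$merged, compiled$filters)
      msg <- apply_filters(msg, settings)
      if (!is.null(stmt$embedded_set)) {
        variables[[stmt$embedded_set$variable]] <-
          extract_variable(msg, stmt$embedded_set$jsonpath)
      }
      results <- c(results, list(msg))
    } else if (inherits(stmt, "ql_create_graph")) {
      val <- variables[[stmt$from_variable]]
      kg <- if (inherits(val, "knowledge_graph")) val else {
        abort_compile(paste0("variable '", stmt$from_variable,
                             "' does not hold a knowledge graph"))
      }
      store_named_graph(store, stmt$name, kg)
    }
  }
  structure(
    list(message = if (length(results)) results[[length(results)]] else NULL,
         messages = results, variables = variables, store = store),
    class = "program_result"
  )
}

# Deferred result filters from unclassified constraints: numeric comparisons
# against answer scores or edge weights by attribute name; rows failing are
# dropped. Named filters understood: score, edge_weight (minimum over the
# row's bound edges).
apply_result_filters <- function(message, filters) {
  if (!length(filters) || nrow(message$knowledge_map) == 0) return(message)
  cmp <- function(op, a, b) switch(op,
    "=" = a == b, "!=" = a != b, "<" = a < b, ">" = a > b,
    "<=" = a <= b, ">=" = a >= b)
  weights <- stats::setNames(message$knowledge_graph$edges$weight,
                             edge_key(message$knowledge_graph$edges))
  km <- message$knowledge_map
  keep <- rep(TRUE, nrow(km))
  for (f in filters) {
    rhs <- value_data(f$rhs)
    lhs_name <- paste(f$lhs, collapse = ".")
    vals <- switch(lhs_name,
      score = km$score,
      edge_weight = vapply(km$edge_bindings, function(eb) {
        w <- weights[unlist(eb)]
        if (!length(w) || all(is.na(w))) NA_real_ else min(w, na.rm = TRUE)
      }, numeric(1)),
      NULL
    )
    if (is.null(vals)) {
      rlang::warn(paste0("ignoring unrecognized result filter: ", lhs_name),
                  class = "kgql_filter_warning")
      next
    }
    ok <- cmp(f$op, vals, as.numeric(rhs))
    ok[is.na(ok)] <- TRUE  # rows without the quantity pass
    keep <- keep & ok
  }
  kg_message(message$query_graph, message$knowledge_graph, km[keep, ])
}

#' @export
print.program_result <- function(x, ...) {
  cat("<program_result> ", length(x$messages), " select result(s), ",
      length(x$variables), " variable(s)\n", sep = "")
  if (!is.null(x$message)) print(x$message)
  invisible(x)
}

#' Run a query file end to end and write the result
#'
#' The file-level driver behind the command-line interface: loads the
#' registry, runs the program, and writes the final merged, filtered
#' message (or a table / GraphML export) to `output_path`.
#'
#' @param query_path Path to a `.tql` query file.
#' @param registry A [source_registry()] or path to a registry YAML.
#' @param output_path Output file path (`NULL` returns the result only).
#' @param output_format `"message-json"`, `"tsv-table"`, or `"graphml"`.
#' @param settings [filter_settings()].
#' @param cache_mode `"on"`, `"off"`, or `"clear-first"`.
#' @param cache A [query_cache()] to reuse across runs (optional).
#' @param model A [concept_model()].
#' @return The `program_result`, invisibly.
#' @export
run_query_file <- function(query_path, registry, output_path = NULL,
                           output_format = c("message-json", "tsv-table",
                                             "graphml"),
                           settings = filter_settings(),
                           cache_mode = c("on", "off", "clear-first"),
                           cache = query_cache(),
                           model = default_concept_model()) {
  output_format <- match.arg(output_format)
  cache_mode <- match.arg(cache_mode)
  if (is.character(registry)) registry <- read_registry(registry, model)
  text <- paste(readLines(query_path, warn = FALSE), collapse = "\n")
  if (cache_mode == "off") cache_control(cache, "disable")
  if (cache_mode == "clear-first") cache_control(cache, "clear")
  res <- run_program(text, registry, model = model, cache = cache,
                     settings = settings)
  if (!is.null(output_path) && !is.null(res$message)) {
    switch(output_format,
      "message-json" = write_message(res$message, output_path),
      "tsv-table" = write_table_tsv(res$message, output_path),
      "graphml" = write_graphml(res$message$knowledge_graph, output_path)
    )
  }
  invisible(res)
}

#' Export a knowledge graph as GraphML
#'
#' @param kg A [knowledge_graph()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(kg, path) {
  g <- igraph::graph_from_data_frame(
    d = cbind(kg$edges[, c("subject", "object")],
              predicate = kg$edges$predicate,
              weight_attr = ifelse(is.na(kg$edges$weight), 1,
                                   kg$edges$weight),
              source = ifelse(is.na(kg$edges$source), "", kg$edges$source)),
    vertices = data.frame(name = kg$nodes$id, concept = kg$nodes$concept,
                          label = kg$nodes$label),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
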