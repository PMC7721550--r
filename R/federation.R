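#' Query result cache
#'
#' Whole-query results are cached under a key derived from the raw query
#' text only (SHA-256 of the exact bytes): re-running a byte-identical query
#' serves the stored merged message without invoking any source, while any
#' textual change — even whitespace — circumvents the cache. The cache can
#' be temporarily disabled (entries kept, neither served nor stored) or
#' cleared entirely.
#'
#' @param enabled Start enabled?
#' @return A `query_cache` (environment-backed; reference semantics).
#' @export
query_cache <- function(enabled = TRUE) {
  env <- new.env(parent = emptyenv())
  env$entries <- new.env(parent = emptyenv())
  env$enabled <- isTRUE(enabled)
  structure(env, class = "query_cache")
}

cache_key <- function(query_text) cli::hash_sha256(query_text)

cache_lookup <- function(cache, query_text) {
  if (!cache$enabled) return(NULL)
  get0(cache_key(query_text), envir = cache$entries, ifnotfound = NULL)
}

cache_store <- function(cache, query_text, serialized) {
  if (cache$enabled) {
    assign(cache_key(query_text), serialized, envir = cache$entries)
  }
  invisible(cache)
}

#' Cache administration
#'
#' @param cache A [query_cache()].
#' @param action `"disable"`, `"enable"`, or `"clear"`. Disabling keeps the
#'   stored entries but stops serving and storing; clearing empties them.
#' @return The updated cache, invisibly.
#' @export
cache_control <- function(cache, action = c("disable", "enable", "clear")) {
  action <- match.arg(action)
  switch(action,
    disable = cache$enabled <- FALSE,
    enable = cache$enabled <- TRUE,
    clear = cache$entries <- new.env(parent = emptyenv())
  )
  invisible(cache)
}

#' Number of entries currently stored
#' @param cache A [query_cache()].
#' @return Integer count.
#' @export
cache_size <- function(cache) length(ls(cache$entries))

#' @export
print.query_cache <- function(x, ...) {
  cat("<query_cache> ", cache_size(x), " entries, ",
      if (x$enabled) "enabled" else "disabled", "\n", sep = "")
  invisible(x)
}

# ---- invocation -------------------------------------------------------------

#' Invoke one knowledge source for one plan segment
#'
#' Attaches pinned identifiers (from constraints or the previous segment)
#' to the fragment's query nodes, calls the source, and enforces the
#' backplane contract on the response: node concepts compatible with the
#' fragment, referential closure, every edge stamped with this source's
#' name, every answer row binding every fragment alias. A violating
#' response is quarantined with a federation error rather than merged.
#'
#' @param source A [knowledge_source()].
#' @param segment A plan segment from [plan_query()].
#' @param pinned Named list: alias -> character vector of CURIEs to pin
#'   (intersected with compile-time pins).
#' @param model A [concept_model()] for the concept-compatibility check.
#' @return The source's validated [kg_message()].
#' @export
invoke_source <- function(source, segment, pinned = list(),
                          model = default_concept_model()) {
  if (!identical(segment$service, source$name)) {
    abort_federation(paste0("segment for '", segment$service,
                            "' sent to source '", source$name, "'"))
  }
  fragment <- segment$sub_path
  for (alias in names(pinned)) {
    k <- match(alias, fragment$nodes$alias)
    if (is.na(k)) next
    existing <- fragment$nodes$pinned_ids[[k]]
    ids <- unique(as.character(pinned[[alias]]))
    if (!is.null(existing)) ids <- intersect(existing, ids)
    fragment$nodes$pinned_ids[[k]] <- ids
  }
  count_invocation(source)
  response <- source$invoke(fragment, segment$options)
  validate_source_response(source, fragment, response, model)
  response
}

validate_source_response <- function(source, fragment, response, model) {
  quarantine <- function(msg) {
    abort_federation(paste0("response from '", source$name,
                            "' violates the source contract: ", msg))
  }
  if (!inherits(response, "kg_message")) quarantine("not a message")
  ok <- tryCatch({ validate_message(response); TRUE },
                 kgql_error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) quarantine(ok)
  if (nrow(response$knowledge_graph$edges) &&
      any(is.na(response$knowledge_graph$edges$source) |
            response$knowledge_graph$edges$source != source$name)) {
    quarantine("edge without this source's provenance stamp")
  }
  if (!identical(response$query_graph$nodes$alias, fragment$nodes$alias)) {
    quarantine("response answers a different fragment")
  }
  # Returned node concepts must be compatible with the query node they bind,
  # and bindings must respect pinned ids. Checked per alias over the unique
  # bound ids, so validation stays linear in the answer count.
  concept_of <- stats::setNames(response$knowledge_graph$nodes$concept,
                                response$knowledge_graph$nodes$id)
  if (nrow(response$knowledge_map)) {
    for (k in seq_len(nrow(fragment$nodes))) {
      alias <- fragment$nodes$alias[k]
      qc <- fragment$nodes$concept[k]
      ids <- unique(vapply(response$knowledge_map$node_bindings,
                           function(b) b[[alias]], character(1)))
      bad <- ids[!concept_compatible(model, unname(concept_of[ids]), qc)]
      if (length(bad)) {
        quarantine(paste0("node ", bad[1], " of concept ",
                          concept_of[[bad[1]]], " bound to query concept ", qc))
      }
      pins <- fragment$nodes$pinned_ids[[k]]
      if (!is.null(pins) && !all(ids %in% pins)) {
        quarantine(paste0("binding outside pinned ids for alias ", alias))
      }
    }
  }
  invisible(response)
}

#' Execute a plan segment by segment
#'
#' Runs each segment against its registered source, pinning each segment's
#' join alias to the distinct node identifiers bound to that alias by the
#' previous segment (forward binding propagation). An upstream segment with
#' an empty answer set short-circuits: downstream sources are not invoked
#' and the overall result is empty. When the cache holds an entry for the
#' raw `query_text`, no source is invoked at all and the stored merged
#' message is returned; otherwise the merged result is stored after merging.
#'
#' @param plan A [plan_query()] result.
#' @param registry A [source_registry()].
#' @param cache A [query_cache()], or `NULL` for no caching.
#' @param query_text Raw query text keying the cache (required when `cache`
#'   is given).
#' @param model A [concept_model()] for merging.
#' @return An `execution_result`: `segments` (list of per-segment messages),
#'   `merged` (the final [kg_message()]), `cache_hit` (logical).
#' @export
execute_plan <- function(plan, registry, cache = NULL, query_text = NULL,
                         model = default_concept_model()) {
  for (seg in plan$segments) registry_get(registry, seg$service)
  if (!is.null(cache) && !is.null(query_text)) {
    hit <- cache_lookup(cache, query_text)
    if (!is.null(hit)) {
      return(structure(list(segments = list(),
                            merged = read_message(hit),
                            cache_hit = TRUE),
                       class = "execution_result"))
    }
  }
  full_qg <- plan$query$query_graph
  messages <- list()
  prev_ids <- NULL
  short_circuited <- FALSE
  for (i in seq_along(plan$segments)) {
    seg <- plan$segments[[i]]
    pinned <- list()
    if (!is.null(seg$join_alias)) {
      pinned[[seg$join_alias]] <- prev_ids
    }
    msg <- invoke_source(registry_get(registry, seg$service), seg, pinned,
                         model = model)
    messages[[i]] <- msg
    if (nrow(msg$knowledge_map) == 0) {
      short_circuited <- TRUE
      break
    }
    last_alias <- seg$sub_path$nodes$alias[nrow(seg$sub_path$nodes)]
    prev_ids <- sort(unique(purrr::map_chr(msg$knowledge_map$node_bindings,
                                           last_alias)))
  }
  merged <- if (short_circuited) {
    kg_message(full_qg, empty_kg(), NULL)
  } else {
    merge_messages(messages, full_qg, model = model)
  }
  if (!is.null(cache) && !is.null(query_text)) {
    cache_store(cache, query_text, write_message(merged))
  }
  structure(list(segments = messages, merged = merged, cache_hit = FALSE),
            class = "execution_result")
}

#' @export
print.execution_result <- function(x, ...) {
  cat("<execution_result> ", length(x$segments), " segment message(s)",
      if (x$cache_hit) " [cache hit]", "\n", sep = "")
  print(x$merged)
  invisible(x)
}
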