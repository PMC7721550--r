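#' Compile a SELECT statement into an executable query
#'
#' Builds the linear [query_graph()] from the statement's concept path
#' (auto-aliasing repeated concepts with numeric suffixes) and classifies
#' each WHERE constraint:
#'
#' * lhs equal to a path alias with `=` — the value pins that query node's
#'   identifiers (`pinned_ids`);
#' * dotted lhs whose prefix names a declared service — a service-scoped
#'   option forwarded with that service's invocation (e.g. cohort feature
#'   parameters for a clinical endpoint);
#' * anything else — a deferred result filter applied after execution.
#'
#' @param stmt A `ql_select` node from [parse_program()].
#' @param model A [concept_model()]; every path concept must exist in it.
#' @param variables Named list: the program's variable store, used to
#'   resolve `$name` references at compile time.
#' @param services Character vector of declared service names used to
#'   validate dotted option prefixes; `NULL` skips the check.
#' @return A `compiled_query`: `query_graph`, `service`, `options` (tibble
#'   `service`/`name`/`value`), `filters` (list of constraints), and the
#'   originating statement.
#' @export
compile_select <- function(stmt, model, variables = list(), services = NULL) {
  stopifnot(inherits(stmt, "ql_select"))
  resolve <- function(v, pos) {
    if (v$type == "var") {
      if (!v$text %in% names(variables)) {
        abort_compile(paste0("variable '$", v$text, "' is not bound"),
                      line = pos[1], col = pos[2])
      }
      return(variables[[v$text]])
    }
    value_data(v)
  }

  # Path -> query nodes with auto-aliases.
  concepts <- purrr::map_chr(stmt$path, function(s) normalize_name(s$concept))
  for (k in seq_along(concepts)) {
    if (!has_concept(model, concepts[k])) {
      pos <- attr(stmt$path[[k]], "pos") %||% c(NA_integer_, NA_integer_)
      abort_compile(paste0("unknown concept: ", concepts[k]),
                    line = pos[1], col = pos[2])
    }
  }
  aliases <- character(length(concepts))
  seen <- integer()
  for (k in seq_along(concepts)) {
    if (!is.null(stmt$path[[k]]$alias)) {
      aliases[k] <- stmt$path[[k]]$alias
    } else {
      cnt <- sum(concepts[seq_len(k)] == concepts[k])
      aliases[k] <- if (cnt == 1) concepts[k] else paste0(concepts[k], "_", cnt)
    }
  }
  if (anyDuplicated(aliases)) {
    k <- which(duplicated(aliases))[1]
    dup_pos <- attr(stmt$path[[k]], "pos") %||% c(NA_integer_, NA_integer_)
    abort_compile(paste0("alias '", aliases[k], "' used twice: query graphs ",
                         "are restricted to a single linear path"),
                  line = dup_pos[1], col = dup_pos[2])
  }
  predicates <- purrr::map_chr(stmt$hops, function(p) {
    if (is.null(p)) NA_character_ else normalize_name(p)
  })
  for (p in stats::na.omit(predicates)) {
    if (!has_predicate(model, p)) {
      ppos <- attr(stmt$path[[1]], "pos") %||% c(NA_integer_, NA_integer_)
      abort_compile(paste0("unknown predicate: ", p),
                    line = ppos[1], col = ppos[2])
    }
  }

  pinned <- stats::setNames(rep(list(NULL), length(aliases)), aliases)
  options <- tibble::tibble(service = character(), name = character(),
                            value = list())
  filters <- list()
  for (co in stmt$constraints) {
    pos <- attr(co, "pos") %||% c(NA_integer_, NA_integer_)
    val <- resolve(co$rhs, pos)
    if (length(co$lhs) == 1 && co$lhs %in% aliases && co$op == "=") {
      pinned[[co$lhs]] <- unique(c(pinned[[co$lhs]], as.character(val)))
    } else if (length(co$lhs) > 1) {
      prefix <- co$lhs[1]
      if (!is.null(services) && !prefix %in% services) {
        abort_compile(paste0("option prefix '", prefix,
                             "' matches no declared service"),
                      line = pos[1], col = pos[2])
      }
      options <- dplyr::bind_rows(options, tibble::tibble(
        service = prefix, name = paste(co$lhs[-1], collapse = "."),
        value = list(val)))
    } else {
      co$rhs <- ql_value(if (is.character(val)) "string" else "number",
                         as.character(val))
      filters <- c(filters, list(co))
    }
  }

  qg <- query_graph(
    nodes = tibble::tibble(alias = aliases, concept = concepts,
                           pinned_ids = unname(pinned)),
    edges = if (length(aliases) > 1) tibble::tibble(
      from_alias = aliases[-length(aliases)],
      to_alias = aliases[-1],
      predicate = predicates
    ) else NULL
  )
  structure(
    list(query_graph = qg, service = stmt$service, options = options,
         filters = filters, statement = stmt),
    class = "compiled_query"
  )
}

#' @export
print.compiled_query <- function(x, ...) {
  cat("<compiled_query> service: ", x$service, "\n", sep = "")
  print(x$query_graph)
  if (nrow(x$options)) {
    cat("  options: ", paste(paste0(x$options$service, ".", x$options$name),
                             collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
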