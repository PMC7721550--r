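#' Hierarchical concept vocabulary
#'
#' A minimal Biolink-style vocabulary: a single-inheritance tree of entity
#' concepts rooted at `named_thing` and a parallel tree of predicates rooted
#' at `related_to`. The model is the type system for query graphs, knowledge
#' graphs, and service transition maps: a query node typed `disease` accepts
#' any node whose concept is compatible with `disease` under the hierarchy.
#'
#' Names are normalized on the way in: lower-cased, spaces become
#' underscores, so prose names like `"chemical substance"` map onto the
#' identifier `chemical_substance`.
#'
#' @param concepts Data frame (or tibble) with columns `name` and `parent`;
#'   `parent` may be `NA` to attach the entry directly to the root.
#' @param predicates Same layout as `concepts`, for predicates.
#' @param root_concept,root_predicate Names of the two hierarchy roots.
#' @return A `concept_model` object.
#' @examples
#' m <- concept_model(
#'   concepts = data.frame(name = c("disease", "gene"), parent = NA),
#'   predicates = data.frame(name = "affects", parent = NA)
#' )
#' is_subtype(m, "disease", "named_thing")
#' @export
concept_model <- function(concepts = NULL, predicates = NULL,
                          root_concept = "named_thing",
                          root_predicate = "related_to") {
  model <- structure(
    list(
      concepts = build_hierarchy(concepts, root_concept, "concept"),
      predicates = build_hierarchy(predicates, root_predicate, "predicate"),
      root_concept = root_concept,
      root_predicate = root_predicate
    ),
    class = "concept_model"
  )
  model
}

# parent_of: named character, root maps to NA; validates the tree.
build_hierarchy <- function(entries, root, what) {
  parent_of <- stats::setNames(NA_character_, root)
  if (!is.null(entries) && nrow(as.data.frame(entries)) > 0) {
    entries <- as.data.frame(entries)
    if (!"parent" %in% names(entries)) entries$parent <- NA_character_
    nm <- normalize_name(entries$name)
    pa <- ifelse(is.na(entries$parent) | entries$parent == "", root,
                 normalize_name(entries$parent))
    if (anyDuplicated(nm)) {
      abort_model(paste0("duplicate ", what, " name: ",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    }
    if (root %in% nm) abort_model(paste0(what, " '", root, "' clashes with the root"))
    parent_of <- c(parent_of, stats::setNames(pa, nm))
  }
  unknown <- setdiff(stats::na.omit(unname(parent_of)), names(parent_of))
  if (length(unknown)) {
    abort_model(paste0("unknown parent ", what, ": ", paste(unknown, collapse = ", ")))
  }
  # Walk every chain to the root; revisiting a name inside one walk is a cycle.
  for (start in names(parent_of)) {
    seen <- character()
    cur <- start
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) {
        abort_model(paste0("cycle in ", what, " hierarchy: ",
                           paste(c(seen, cur), collapse = " -> ")))
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  parent_of
}

#' Normalize a vocabulary name
#'
#' Lower-cases and replaces runs of spaces/hyphens with underscores, so the
#' field's prose spellings ("chemical substance") become identifiers.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

#' Load a concept model from a vocabulary document
#'
#' Reads a YAML or JSON document with two top-level lists, `concepts` and
#' `predicates`, each entry `{name, parent}`. Entries without a parent attach
#' to the root. The packaged default vocabulary is returned by
#' [default_concept_model()].
#'
#' @param path Path to the YAML/JSON document.
#' @return A `concept_model`.
#' @export
load_concept_model <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_entry_df <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    tibble::tibble(
      name = purrr::map_chr(x, "name"),
      parent = purrr::map_chr(x, function(e) e$parent %||% NA_character_)
    )
  }
  concept_model(
    concepts = as_entry_df(doc$concepts),
    predicates = as_entry_df(doc$predicates),
    root_concept = doc$root_concept %||% "named_thing",
    root_predicate = doc$root_predicate %||% "related_to"
  )
}

#' The vocabulary shipped with the package
#'
#' A compact stand-in for an upper-level biomedical ontology: ~15 entity
#' concepts (disease, gene, chemical_substance, ...) and ~10 predicates,
#' enough for the worked examples and the test federations. Not a full
#' Biolink import.
#'
#' @return A `concept_model`.
#' @export
default_concept_model <- function() {
  load_concept_model(system.file("extdata", "vocabulary.yaml", package = "kgql"))
}

#' @export
print.concept_model <- function(x, ...) {
  cat("<concept_model> ", length(x$concepts), " concepts (root: ", x$root_concept,
      "), ", length(x$predicates), " predicates (root: ", x$root_predicate, ")\n",
      sep = "")
  invisible(x)
}

model_concepts <- function(model) names(model$concepts)
model_predicates <- function(model) names(model$predicates)

has_concept <- function(model, name) name %in% names(model$concepts)
has_predicate <- function(model, name) name %in% names(model$predicates)

ancestor_chain <- function(parent_of, name) {
  chain <- name
  cur <- name
  while (!is.na(parent_of[[cur]])) {
    cur <- parent_of[[cur]]
    chain <- c(chain, cur)
  }
  chain
}

#' Subtype test in the concept hierarchy
#'
#' `TRUE` iff `ancestor` lies on `child`'s parent chain, or the two are equal
#' (reflexive). Vectorized over `child`.
#'
#' @param model A `concept_model`.
#' @param child,ancestor Concept names (already normalized).
#' @param predicate Use the predicate hierarchy instead of the concept one.
#' @return Logical vector.
#' @export
is_subtype <- function(model, child, ancestor, predicate = FALSE) {
  parent_of <- if (predicate) model$predicates else model$concepts
  what <- if (predicate) "predicate" else "concept"
  for (nm in unique(c(child, ancestor))) {
    if (!nm %in% names(parent_of)) abort_lookup(paste0("unknown ", what, ": ", nm))
  }
  n <- max(length(child), length(ancestor))
  child <- rep_len(child, n)
  ancestor <- rep_len(ancestor, n)
  vapply(seq_len(n), function(i) {
    ancestor[[i]] %in% ancestor_chain(parent_of, child[[i]])
  }, logical(1))
}

# Bidirectional compatibility: endpoints advertise at differing granularity,
# so a query concept may be more general or more specific than the advertised
# or asserted one. Shared by the planner, the fixture sources and the oracle.
concept_compatible <- function(model, a, b) {
  is_subtype(model, a, b) | is_subtype(model, b, a)
}

predicate_compatible <- function(model, a, b) {
  if (is.null(a) || is.na(a) || is.null(b) || is.na(b)) return(TRUE)
  is_subtype(model, a, b, predicate = TRUE) ||
    is_subtype(model, b, a, predicate = TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
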