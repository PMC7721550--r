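# Recursive-descent parser and pretty-printer.
#
# Grammar (keywords case-insensitive, `#` line comments):
#   program     := statement+
#   statement   := set_stmt | select_stmt | create_graph_stmt
#   set_stmt    := SET ident '=' value
#   select_stmt := SELECT concept[':' alias]
#                    ( ('->' | '-[' predicate ']->') concept[':' alias] )*
#                  FROM string
#                  (WHERE constraint (AND constraint)*)?
#                  (SET (string AS)? ident)?
#   create_graph_stmt := CREATE GRAPH ident AT string FROM ident
#   constraint  := ident ('.' ident)* op value
#   op          := '=' | '<' | '>' | '<=' | '>=' | '!='
#   value       := string | number | $ident
#
# `$ident` variable references must be assigned by an earlier statement.
# AST nodes carry their source position as a `pos` attribute (line, col),
# which is ignored by equality comparisons (see ast_strip_pos()).

ql_value <- function(type, text) {
  structure(list(type = type, text = text), class = "ql_value")
}

value_data <- function(v) {
  switch(v$type,
    string = v$text,
    number = as.numeric(v$text),
    var = v$text  # resolved later against the variable store
  )
}

with_pos <- function(node, tok) {
  attr(node, "pos") <- c(line = tok$line, col = tok$col)
  node
}

token_pos <- function(tok) list(line = tok$line, col = tok$col)

#' Parse query-language source into a program AST
#'
#' @param x Source text, or a token tibble from [tokenize()].
#' @return A `ql_program` whose `statements` are `ql_set`, `ql_select` or
#'   `ql_create_graph` nodes.
#' @export
parse_program <- function(x) {
  toks <- if (is.character(x)) tokenize(x) else x
  toks <- toks[toks$kind != "NEWLINE", ]
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$toks <- toks
  st$vars <- character()

  cur <- function() {
    if (st$i > nrow(st$toks)) return(NULL)
    as.list(st$toks[st$i, ])
  }
  peek_kind <- function(k = 0L) {
    j <- st$i + k
    if (j > nrow(st$toks)) "" else st$toks$kind[j]
  }
  peek_text <- function(k = 0L) {
    j <- st$i + k
    if (j > nrow(st$toks)) "" else st$toks$text[j]
  }
  last_tok <- function() as.list(st$toks[max(1L, min(st$i, nrow(st$toks))), ])
  fail <- function(msg) {
    tk <- cur()
    if (is.null(tk)) {
      tk <- if (nrow(st$toks)) last_tok() else list(line = 1L, col = 1L)
      abort_parse(paste0(msg, ", found end of input"),
                  line = tk$line, col = tk$col)
    }
    abort_parse(paste0(msg, ", found '", tk$text, "'"),
                line = tk$line, col = tk$col)
  }
  advance <- function() { tk <- cur(); st$i <- st$i + 1L; tk }
  expect <- function(kind, text = NULL) {
    tk <- cur()
    ok <- !is.null(tk) && tk$kind == kind && (is.null(text) || tk$text == text)
    if (!ok) fail(paste0("expected ", if (is.null(text)) kind else paste0("'", text, "'")))
    advance()
  }
  parse_value <- function() {
    tk <- cur()
    if (is.null(tk)) fail("expected a literal or $variable")
    if (tk$kind == "STRING") { advance(); return(ql_value("string", tk$text)) }
    if (tk$kind == "NUMBER") { advance(); return(ql_value("number", tk$text)) }
    if (tk$kind == "IDENT" && startsWith(tk$text, "$")) {
      advance()
      nm <- substring(tk$text, 2L)
      if (!nm %in% st$vars) {
        abort_parse(paste0("variable '$", nm, "' referenced before assignment"),
                    line = tk$line, col = tk$col)
      }
      return(ql_value("var", nm))
    }
    fail("expected a literal or $variable")
  }
  parse_concept_spec <- function() {
    tk <- expect("IDENT")
    alias <- NULL
    if (peek_kind() == "OP" && peek_text() == ":") {
      advance()
      alias <- expect("IDENT")$text
    }
    with_pos(list(concept = tk$text, alias = alias), tk)
  }
  parse_constraint <- function() {
    tk <- expect("IDENT")
    lhs <- tk$text
    while (peek_kind() == "DOT") {
      advance()
      lhs <- c(lhs, expect("IDENT")$text)
    }
    op_tok <- cur()
    if (is.null(op_tok) ||
        !(op_tok$kind == "EQUALS" ||
          (op_tok$kind == "OP" && op_tok$text %in% c("<", ">", "<=", ">=", "!=")))) {
      fail("expected a comparison operator")
    }
    advance()
    rhs <- parse_value()
    with_pos(structure(list(lhs = lhs, op = op_tok$text, rhs = rhs),
                       class = "ql_constraint"), tk)
  }
  parse_set_stmt <- function() {
    tk <- expect("KEYWORD", "set")
    var <- expect("IDENT")$text
    expect("EQUALS")
    val <- parse_value()
    st$vars <- union(st$vars, var)
    with_pos(structure(list(variable = var, value = val), class = "ql_set"), tk)
  }
  parse_select_stmt <- function() {
    tk <- expect("KEYWORD", "select")
    path <- list(parse_concept_spec())
    hops <- list()
    repeat {
      if (peek_kind() == "ARROW") {
        advance()
        hops <- c(hops, list(NULL))
      } else if (peek_kind() == "OP" && peek_text() == "-" &&
                 peek_kind(1L) == "LBRACKET") {
        advance(); advance()
        pred <- expect("IDENT")$text
        expect("RBRACKET")
        expect("ARROW")
        hops <- c(hops, list(pred))
      } else break
      path <- c(path, list(parse_concept_spec()))
    }
    expect("KEYWORD", "from")
    service <- expect("STRING")$text
    constraints <- list()
    if (peek_kind() == "KEYWORD" && peek_text() == "where") {
      advance()
      constraints <- list(parse_constraint())
      while (peek_kind() == "KEYWORD" && peek_text() == "and") {
        advance()
        constraints <- c(constraints, list(parse_constraint()))
      }
    }
    embedded <- NULL
    # Embedded `set` has no '='; a following top-level set statement does.
    if (peek_kind() == "KEYWORD" && peek_text() == "set" &&
        !(peek_kind(1L) == "IDENT" && peek_kind(2L) == "EQUALS")) {
      advance()
      if (peek_kind() == "STRING") {
        jp <- advance()$text
        expect("KEYWORD", "as")
        var <- expect("IDENT")$text
        embedded <- list(jsonpath = jp, variable = var)
      } else {
        var <- expect("IDENT")$text
        embedded <- list(jsonpath = NULL, variable = var)
      }
      st$vars <- union(st$vars, embedded$variable)
    }
    with_pos(structure(list(path = path, hops = hops, service = service,
                            constraints = constraints, embedded_set = embedded),
                       class = "ql_select"), tk)
  }
  parse_create_graph <- function() {
    tk <- expect("KEYWORD", "create")
    expect("KEYWORD", "graph")
    name <- expect("IDENT")$text
    expect("KEYWORD", "at")
    at <- expect("STRING")$text
    expect("KEYWORD", "from")
    var <- expect("IDENT")$text
    if (!var %in% st$vars) {
      tk2 <- last_tok()
      abort_parse(paste0("variable '", var, "' referenced before assignment"),
                  line = tk2$line, col = tk2$col)
    }
    with_pos(structure(list(name = name, at = at, from_variable = var),
                       class = "ql_create_graph"), tk)
  }

  statements <- list()
  repeat {
    tk <- cur()
    if (is.null(tk)) break
    if (tk$kind != "KEYWORD") fail("expected a statement keyword")
    stmt <- switch(tk$text,
      set = parse_set_stmt(),
      select = parse_select_stmt(),
      create = parse_create_graph(),
      fail("expected 'set', 'select' or 'create'")
    )
    statements <- c(statements, list(stmt))
  }
  if (length(statements) == 0) {
    abort_parse("program must contain at least one statement", line = 1L, col = 1L)
  }
  structure(list(statements = statements), class = "ql_program")
}

# ---- pretty-printer ---------------------------------------------------------

format_value <- function(v) {
  switch(v$type,
    string = paste0('"', v$text, '"'),
    number = v$text,
    var = paste0("$", v$text)
  )
}

format_statement <- function(stmt) {
  if (inherits(stmt, "ql_set")) {
    return(paste0("set ", stmt$variable, " = ", format_value(stmt$value)))
  }
  if (inherits(stmt, "ql_create_graph")) {
    return(paste0("create graph ", stmt$name, ' at "', stmt$at,
                  '" from ', stmt$from_variable))
  }
  spec_txt <- function(s) {
    if (is.null(s$alias)) s$concept else paste0(s$concept, ":", s$alias)
  }
  out <- paste0("select ", spec_txt(stmt$path[[1]]))
  for (i in seq_along(stmt$hops)) {
    p <- stmt$hops[[i]]
    arrow <- if (is.null(p)) "->" else paste0("-[", p, "]->")
    out <- paste0(out, arrow, spec_txt(stmt$path[[i + 1]]))
  }
  out <- paste0(out, ' from "', stmt$service, '"')
  if (length(stmt$constraints)) {
    cons <- purrr::map_chr(stmt$constraints, function(co) {
      paste0(paste(co$lhs, collapse = "."), " ", co$op, " ", format_value(co$rhs))
    })
    out <- paste0(out, " where ", paste(cons, collapse = " and "))
  }
  if (!is.null(stmt$embedded_set)) {
    es <- stmt$embedded_set
    out <- if (is.null(es$jsonpath)) {
      paste0(out, " set ", es$variable)
    } else {
      paste0(out, ' set "', es$jsonpath, '" as ', es$variable)
    }
  }
  out
}

#' Render a program AST back to source text
#'
#' Deterministic normal form: one statement per line, lower-case keywords.
#' `parse_program(format_program(ast))` reproduces `ast` (up to source
#' positions).
#'
#' @param program A `ql_program`.
#' @return A single string of query source.
#' @export
format_program <- function(program) {
  paste(purrr::map_chr(program$statements, format_statement), collapse = "\n")
}

#' @export
print.ql_program <- function(x, ...) {
  cat(format_program(x), "\n", sep = "")
  invisible(x)
}

# Drop source-position attributes so structurally equal ASTs compare equal.
ast_strip_pos <- function(x) {
  attr(x, "pos") <- NULL
  if (is.list(x)) {
    for (i in seq_along(x)) x[i] <- list(ast_strip_pos(x[[i]]))
  }
  x
}
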