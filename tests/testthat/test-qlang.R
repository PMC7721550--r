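test_that("lexer produces the expected token stream", {
  toks <- tokenize('select disease from "/schema"')
  expect_identical(toks$kind, c("KEYWORD", "IDENT", "KEYWORD", "STRING"))
  expect_identical(toks$text, c("select", "disease", "from", "/schema"))
  expect_identical(toks$line, rep(1L, 4))
  expect_identical(toks$col, c(1L, 8L, 16L, 21L))

  expect_identical(nrow(tokenize("")), 0L)

  toks2 <- tokenize("select disease-[affects]->gene from 'x'")
  expect_true(all(c("OP", "LBRACKET", "RBRACKET", "ARROW") %in% toks2$kind))

  # keywords are case-insensitive; comments are skipped
  toks3 <- tokenize("SELECT x FROM 'y' # trailing comment")
  expect_identical(toks3$kind[1], "KEYWORD")
  expect_identical(toks3$text[1], "select")
  expect_identical(nrow(toks3), 4L)
})

test_that("lexical errors carry positions", {
  err <- tryCatch(tokenize('set x = "MONDO'), condition = function(e) e)
  expect_s3_class(err, "kgql_lex_error")
  expect_identical(err$line, 1L)
  expect_identical(err$col, 9L)
  expect_error(tokenize("select ^"), class = "kgql_lex_error")
})

test_that("parser builds programs and resolves statement structure", {
  p <- parse_program(paste(
    'set sex = "male"',
    'select population_of_individual_organisms->disease from "/icees"',
    '  where demographic = $sex',
    sep = "\n"))
  expect_length(p$statements, 2)
  expect_s3_class(p$statements[[1]], "ql_set")
  sel <- p$statements[[2]]
  expect_s3_class(sel, "ql_select")
  expect_identical(sel$constraints[[1]]$rhs$type, "var")
  expect_identical(sel$constraints[[1]]$rhs$text, "sex")

  p2 <- parse_program(
    'select disease->gene->chemical_substance from "/robokop"')
  sel2 <- p2$statements[[1]]
  expect_length(sel2$path, 3)
  expect_length(sel2$hops, 2)
  expect_true(all(vapply(sel2$hops, is.null, logical(1))))
})

test_that("syntax errors are positioned and name the expectation", {
  err <- tryCatch(parse_program('select disease-> from "/x"'),
                  condition = function(e) e)
  expect_s3_class(err, "kgql_parse_error")
  expect_false(is.null(err$line))

  expect_error(parse_program('select disease from'),
               class = "kgql_parse_error")
  expect_error(parse_program(""), class = "kgql_parse_error")
  expect_error(parse_program('select d from "/x" where a = $missing'),
               "before assignment", class = "kgql_parse_error")
})

test_that("embedded set is distinguished from a following set statement", {
  p <- parse_program(paste(
    'select disease from "/x" set kg_var',
    'set y = 3',
    sep = "\n"))
  expect_length(p$statements, 2)
  expect_identical(p$statements[[1]]$embedded_set$variable, "kg_var")
  expect_null(p$statements[[1]]$embedded_set$jsonpath)

  p2 <- parse_program(
    'select disease from "/x" set "$.knowledge_graph.nodes[*].id" as ids')
  expect_identical(p2$statements[[1]]$embedded_set$jsonpath,
                   "$.knowledge_graph.nodes[*].id")
})

test_that("compilation classifies constraints into pins, options, filters", {
  m <- the_model
  p <- parse_program(paste(
    'select disease->gene from "/schema"',
    '  where disease = "MONDO:OC"',
    '  and icees.maximum_p_value = 0.5',
    '  and edge_weight >= 0.1',
    sep = "\n"))
  cq <- compile_select(p$statements[[1]], m,
                       services = c("icees", "robokop"))
  expect_identical(cq$query_graph$nodes$pinned_ids[[1]], "MONDO:OC")
  expect_identical(cq$options$service, "icees")
  expect_identical(cq$options$name, "maximum_p_value")
  expect_identical(cq$options$value[[1]], 0.5)
  expect_length(cq$filters, 1)
  expect_identical(cq$filters[[1]]$op, ">=")
})

test_that("compile errors name the offending element with a position", {
  m <- the_model
  p <- parse_program('select diseaze->gene from "/schema"')
  err <- tryCatch(compile_select(p$statements[[1]], m),
                  condition = function(e) e)
  expect_s3_class(err, "kgql_compile_error")
  expect_match(conditionMessage(err), "diseaze")
  expect_false(is.null(err$line))

  p2 <- parse_program('select disease from "/schema" where bogus.opt = 1')
  expect_error(compile_select(p2$statements[[1]], m, services = "icees"),
               "matches no declared service", class = "kgql_compile_error")

  p3 <- parse_program('select disease:x->gene:x from "/schema"')
  expect_error(compile_select(p3$statements[[1]], m),
               "linear path", class = "kgql_compile_error")
})

test_that("repeated concepts get numeric alias suffixes", {
  m <- the_model
  p <- parse_program('select gene->disease->gene from "/schema"')
  cq <- compile_select(p$statements[[1]], m)
  expect_identical(cq$query_graph$nodes$alias, c("gene", "disease", "gene_2"))
})

test_that("pretty-print and parse are mutually inverse on random programs", {
  for (seed in 1:100) {
    ast <- random_program(seed)
    txt <- format_program(ast)
    expect_identical(kgql:::ast_strip_pos(parse_program(txt)), ast,
                     label = paste("seed", seed))
  }
})

test_that("tokenizing concatenated statements equals concatenated streams", {
  for (seed in 1:25) {
    a <- format_program(random_program(seed))
    b <- format_program(random_program(seed + 500))
    joint <- tokenize(paste(a, b, sep = "\n"))
    parts <- dplyr::bind_rows(
      tokenize(a),
      tibble::tibble(kind = "NEWLINE", text = "\n", line = NA_integer_,
                     col = NA_integer_),
      tokenize(b))
    expect_identical(joint$kind, parts$kind)
    expect_identical(joint$text, parts$text)
  }
})
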