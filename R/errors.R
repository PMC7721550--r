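# Condition helpers. Every engine error is an rlang condition with a
# kgql_* class so callers (and the CLI) can dispatch on failure kind.
# Positioned errors (lexer/parser/compiler) carry integer `line` and `col`.

abort_kgql <- function(message, class, ..., line = NULL, col = NULL) {
  if (!is.null(line)) {
    message <- paste0(message, " (line ", line, ", col ", col, ")")
  }
  rlang::abort(message, class = c(class, "kgql_error"), line = line, col = col, ...)
}

abort_model       <- function(msg, ...) abort_kgql(msg, "kgql_model_error", ...)
abort_lookup      <- function(msg, ...) abort_kgql(msg, "kgql_lookup_error", ...)
abort_integrity   <- function(msg, ...) abort_kgql(msg, "kgql_integrity_error", ...)
abort_lex         <- function(msg, ...) abort_kgql(msg, "kgql_lex_error", ...)
abort_parse       <- function(msg, ...) abort_kgql(msg, "kgql_parse_error", ...)
abort_compile     <- function(msg, ...) abort_kgql(msg, "kgql_compile_error", ...)
abort_plan        <- function(msg, ...) abort_kgql(msg, "kgql_plan_error", ...)
abort_registry    <- function(msg, ...) abort_kgql(msg, "kgql_registry_error", ...)
abort_federation  <- function(msg, ...) abort_kgql(msg, "kgql_federation_error", ...)
abort_merge       <- function(msg, ...) abort_kgql(msg, "kgql_merge_error", ...)
abort_settings    <- function(msg, ...) abort_kgql(msg, "kgql_settings_error", ...)
abort_expression  <- function(msg, ...) abort_kgql(msg, "kgql_expression_error", ...)
abort_argument    <- function(msg, ...) abort_kgql(msg, "kgql_argument_error", ...)
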