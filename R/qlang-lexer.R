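# Lexical analyzer for the query language.
#
# Token kinds: KEYWORD, IDENT, ARROW, LBRACKET, RBRACKET, STRING, NUMBER,
# OP, DOT, EQUALS, NEWLINE. Keywords are recognized case-insensitively.
# `$name` variable references are lexed as IDENT tokens whose text keeps the
# leading `$`. `#` starts a line comment. Positions are 1-based.

QL_KEYWORDS <- c("select", "from", "where", "and", "set", "create", "graph",
                 "at", "as")

#' Tokenize query-language source text
#'
#' @param text Query source (a single string; may span lines).
#' @return A tibble of tokens with columns `kind`, `text`, `line`, `col`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L; line <- 1L; col <- 1L
  push <- function(kind, txt, l, c) toks[[length(toks) + 1L]] <<- list(
    kind = kind, text = txt, line = l, col = c)
  peek <- function(k = 1L) if (i + k - 1L <= n) chars[i + k - 1L] else ""
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") {
      push("NEWLINE", "\n", line, col)
      i <- i + 1L; line <- line + 1L; col <- 1L
    } else if (ch %in% c(" ", "\t", "\r")) {
      i <- i + 1L; col <- col + 1L
    } else if (ch == "#") {
      while (i <= n && chars[i] != "\n") { i <- i + 1L; col <- col + 1L }
    } else if (ch %in% c("'", '"')) {
      quote_ch <- ch; l0 <- line; c0 <- col
      j <- i + 1L
      while (j <= n && chars[j] != quote_ch && chars[j] != "\n") j <- j + 1L
      if (j > n || chars[j] != quote_ch) {
        abort_lex("unterminated string literal", line = l0, col = c0)
      }
      push("STRING", paste(chars[(i + 1L):(j - 1L)][seq_len(max(0L, j - i - 1L))],
                           collapse = ""), l0, c0)
      col <- col + (j - i + 1L); i <- j + 1L
    } else if (grepl("[0-9]", ch)) {
      l0 <- line; c0 <- col; j <- i
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j <= n && chars[j] == "." && j + 1L <= n && grepl("[0-9]", chars[j + 1L])) {
        j <- j + 1L
        while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      }
      push("NUMBER", paste(chars[i:(j - 1L)], collapse = ""), l0, c0)
      col <- col + (j - i); i <- j
    } else if (grepl("[A-Za-z_$]", ch)) {
      l0 <- line; c0 <- col; j <- if (ch == "$") i + 1L else i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1L
      if (ch == "$" && j == i + 1L) abort_lex("dangling '$'", line = l0, col = c0)
      word <- paste(chars[i:(j - 1L)], collapse = "")
      kind <- if (tolower(word) %in% QL_KEYWORDS) "KEYWORD" else "IDENT"
      push(kind, if (kind == "KEYWORD") tolower(word) else word, l0, c0)
      col <- col + (j - i); i <- j
    } else if (ch == "-" && peek(2L) == ">") {
      push("ARROW", "->", line, col); i <- i + 2L; col <- col + 2L
    } else if (ch == "-") {
      push("OP", "-", line, col); i <- i + 1L; col <- col + 1L
    } else if (ch == "[") {
      push("LBRACKET", "[", line, col); i <- i + 1L; col <- col + 1L
    } else if (ch == "]") {
      push("RBRACKET", "]", line, col); i <- i + 1L; col <- col + 1L
    } else if (ch == "=") {
      push("EQUALS", "=", line, col); i <- i + 1L; col <- col + 1L
    } else if (ch == ".") {
      push("DOT", ".", line, col); i <- i + 1L; col <- col + 1L
    } else if (ch %in% c("<", ">", "!")) {
      if (peek(2L) == "=") {
        push("OP", paste0(ch, "="), line, col); i <- i + 2L; col <- col + 2L
      } else if (ch == "!") {
        abort_lex("illegal character '!'", line = line, col = col)
      } else {
        push("OP", ch, line, col); i <- i + 1L; col <- col + 1L
      }
    } else if (ch == ":") {
      push("OP", ":", line, col); i <- i + 1L; col <- col + 1L
    } else {
      abort_lex(paste0("illegal character '", ch, "'"), line = line, col = col)
    }
  }
  if (length(toks) == 0) {
    return(tibble::tibble(kind = character(), text = character(),
                          line = integer(), col = integer()))
  }
  tibble::tibble(
    kind = purrr::map_chr(toks, "kind"),
    text = purrr::map_chr(toks, "text"),
    line = purrr::map_int(toks, "line"),
    col = purrr::map_int(toks, "col")
  )
}
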