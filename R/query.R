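# Boolean, field-restricted phrase queries.
#
# The matching dialect deliberately approximates Europe PMC's behaviour:
# text and phrases are lowercased and split on any non-alphanumeric
# character, and a phrase matches iff its token sequence occurs contiguously.
# Hyphens and slashes are therefore token boundaries, so the query term
# "MALDI" hits "MALDI-TOF" and "desorption/ionization" also matches the
# spelled-out "desorption ionization". "MS" matches whole tokens only.
# Publications with an absent methods section fail every METHODS-restricted
# term; there is no fallback to the abstract.

#' Query node constructors
#'
#' Build boolean query ASTs programmatically. `query_term()` creates a
#' phrase term, optionally restricted to the methods section;
#' `query_and()`/`query_or()` combine two or more nodes; `query_not()`
#' negates one.
#'
#' @param phrase Non-empty phrase text.
#' @param field `"all"` (title + abstract + methods) or `"methods"`.
#' @param ... Child nodes (at least two for and/or).
#' @param node A query node to negate.
#' @return An object of class `ldi_query`.
#' @export
query_term <- function(phrase, field = c("all", "methods")) {
  field <- match.arg(field)
  if (!is.character(phrase) || length(phrase) != 1 || !nzchar(trimws(phrase))) {
    stop("query phrase must be a non-empty string", call. = FALSE)
  }
  structure(list(kind = "term", phrase = phrase, field = field),
            class = "ldi_query")
}

#' @rdname query_term
#' @export
query_and <- function(...) {
  kids <- list(...)
  if (length(kids) < 2) stop("AND needs at least two children", call. = FALSE)
  structure(list(kind = "and", children = kids), class = "ldi_query")
}

#' @rdname query_term
#' @export
query_or <- function(...) {
  kids <- list(...)
  if (length(kids) < 2) stop("OR needs at least two children", call. = FALSE)
  structure(list(kind = "or", children = kids), class = "ldi_query")
}

#' @rdname query_term
#' @export
query_not <- function(node) {
  structure(list(kind = "not", child = node), class = "ldi_query")
}

#' @export
format.ldi_query <- function(x, ...) {
  switch(x$kind,
    term = paste0(if (x$field == "methods") "METHODS:" else "",
                  "\"", x$phrase, "\""),
    and = paste0("(", paste(vapply(x$children, format, character(1)),
                            collapse = " AND "), ")"),
    or = paste0("(", paste(vapply(x$children, format, character(1)),
                           collapse = " OR "), ")"),
    not = paste0("NOT ", format(x$child))
  )
}

#' @export
print.ldi_query <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# ---- parser ----------------------------------------------------------------

# Grammar (keywords case-insensitive; NOT binds tighter than AND, AND
# tighter than OR):
#   or_expr  := and_expr (OR and_expr)*
#   and_expr := not_expr (AND not_expr)*
#   not_expr := NOT not_expr | atom
#   atom     := '(' or_expr ')' | [METHODS:] phrase
#   phrase   := "quoted text" | bare-word

lex_query <- function(text) {
  # normalize typographic quotes so queries copied from typeset text parse unchanged
  text <- gsub("[“”„″]", "\"", text)
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("lparen", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("rparen", ")", i); i <- i + 1L; next }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[Mm][Ee][Tt][Hh][Oo][Dd][Ss]:", rest))
    if (length(m) && nzchar(m)) {
      push("fieldprefix", "METHODS", i)
      i <- i + nchar(m)
      next
    }
    if (ch == "\"") {
      close <- regexpr("\"", substr(text, i + 1L, n), fixed = TRUE)
      if (close == -1L) {
        stop("unbalanced quote at position ", i, call. = FALSE)
      }
      push("phrase", substr(text, i + 1L, i + close - 1L), i)
      i <- i + close + 1L
      next
    }
    m <- regmatches(rest, regexpr("^[^\\s()\"]+", rest, perl = TRUE))
    word <- m[1]
    up <- toupper(word)
    if (up %in% c("AND", "OR", "NOT")) {
      push(tolower(up), up, i)
    } else {
      push("phrase", word, i)
    }
    i <- i + nchar(word)
  }
  tokens
}

#' Parse a boolean query string
#'
#' Accepts the query syntax used throughout the shipped technique query set:
#' parentheses, case-insensitive `AND`/`OR`/`NOT`, double-quoted phrases
#' (typographic quotes tolerated), bare single-word terms, and an optional
#' `METHODS:` prefix restricting a term to the methods section. `NOT` binds
#' tighter than `AND`, which binds tighter than `OR`; unprefixed terms
#' search title, abstract and methods.
#'
#' @param text Query string.
#' @return An `ldi_query` AST.
#' @export
#' @examples
#' parse_query('(METHODS:"DART" OR METHODS:"direct analysis in real time")')
#' parse_query('MALDI AND ("small molecule" OR "small molecules")')
parse_query <- function(text) {
  tokens <- lex_query(text)
  pos <- 1L

  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }
  fail <- function(tok, what) {
    at <- if (is.null(tok)) paste0("end of query (position ", nchar(text), ")")
          else paste0("position ", tok$pos)
    stop("query parse error at ", at, ": ", what, call. = FALSE)
  }

  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) kids[[1L]] else do.call(query_or, kids)
  }
  parse_and <- function() {
    kids <- list(parse_not())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      kids[[length(kids) + 1L]] <- parse_not()
    }
    if (length(kids) == 1L) kids[[1L]] else do.call(query_and, kids)
  }
  parse_not <- function() {
    if (!is.null(peek()) && peek()$type == "not") {
      advance()
      return(query_not(parse_not()))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- peek()
    if (is.null(tok)) fail(tok, "expected a term or '('")
    if (tok$type == "lparen") {
      advance()
      node <- parse_or()
      closing <- peek()
      if (is.null(closing) || closing$type != "rparen") {
        fail(closing, "expected ')'")
      }
      advance()
      return(node)
    }
    field <- "all"
    if (tok$type == "fieldprefix") {
      advance()
      field <- "methods"
      tok <- peek()
      if (is.null(tok) || tok$type != "phrase") {
        fail(tok, "expected a phrase after METHODS:")
      }
    }
    if (tok$type == "phrase") {
      advance()
      return(query_term(tok$value, field = field))
    }
    fail(tok, paste0("dangling operator '", tok$value, "'"))
  }

  node <- parse_or()
  tok <- peek()
  if (!is.null(tok)) {
    if (tok$type == "rparen") fail(tok, "unbalanced ')'")
    fail(tok, "unexpected trailing input")
  }
  node
}

# ---- normalization and evaluation ------------------------------------------

normalize_text <- function(x) {
  x <- ifelse(is.na(x), "", x)
  paste0(" ", gsub("[^a-z0-9]+", " ", tolower(x)), " ")
}

normalize_phrase <- function(phrase) {
  p <- gsub("[^a-z0-9]+", " ", tolower(phrase))
  p <- trimws(p)
  if (!nzchar(p)) {
    stop("phrase '", phrase, "' has no searchable tokens", call. = FALSE)
  }
  paste0(" ", p, " ")
}

# Per-corpus token index: the three text fields, lowercased, token-split and
# space-padded so a phrase match is one fixed substring search per field.
# Cached in the corpus's environment; corpora are treated as immutable.
corpus_index <- function(corpus) {
  env <- corpus$.index
  if (is.null(env$built)) {
    pubs <- corpus$publications
    env$title <- normalize_text(pubs$title)
    env$abstract <- normalize_text(pubs$abstract)
    env$methods <- normalize_text(pubs$methods_text)
    env$built <- TRUE
  }
  env
}

#' Evaluate a query over every publication
#'
#' @param corpus An `ldi_corpus`.
#' @param node An `ldi_query` (or a query string).
#' @return Logical vector, one element per publication in corpus order.
#' @export
eval_query <- function(corpus, node) {
  if (is.character(node)) node <- parse_query(node)
  idx <- corpus_index(corpus)
  eval_node(idx, node, n_publications(corpus))
}

eval_node <- function(idx, node, n) {
  switch(node$kind,
    term = {
      needle <- normalize_phrase(node$phrase)
      if (node$field == "methods") {
        grepl(needle, idx$methods, fixed = TRUE)
      } else {
        grepl(needle, idx$title, fixed = TRUE) |
          grepl(needle, idx$abstract, fixed = TRUE) |
          grepl(needle, idx$methods, fixed = TRUE)
      }
    },
    and = Reduce(`&`, lapply(node$children, eval_node, idx = idx, n = n)),
    or = Reduce(`|`, lapply(node$children, eval_node, idx = idx, n = n)),
    not = !eval_node(idx, node$child, n),
    stop("unknown query node kind: ", node$kind)
  )
}

#' Match a single publication against a query
#'
#' @param pub A one-row slice of `corpus$publications`, or a list with
#'   `title`, `abstract` and `methods_text` elements.
#' @param q An `ldi_query`.
#' @return Logical scalar.
#' @export
match_query <- function(pub, q) {
  idx <- list(
    title = normalize_text(pub$title %||% NA_character_),
    abstract = normalize_text(pub$abstract %||% NA_character_),
    methods = normalize_text(pub$methods_text %||% NA_character_)
  )
  as.logical(eval_node(idx, q, 1L))
}

#' Count publications matching a query
#'
#' @param corpus An `ldi_corpus`.
#' @param q An `ldi_query` (or a query string, parsed on the fly).
#' @return Integer count of matching publications.
#' @export
count_matches <- function(corpus, q) {
  if (is.character(q)) q <- parse_query(q)
  sum(eval_query(corpus, q))
}

#' Count co-occurrences of two queries
#'
#' The number of publications matching both `a` and `b`; symmetric, and
#' never larger than either marginal count.
#'
#' @param corpus An `ldi_corpus`.
#' @param a,b Queries (`ldi_query` or strings).
#' @return Integer count.
#' @export
cooccurrence <- function(corpus, a, b) {
  if (is.character(a)) a <- parse_query(a)
  if (is.character(b)) b <- parse_query(b)
  count_matches(corpus, query_and(a, b))
}

# ---- shipped technique query set -------------------------------------------

#' Technique query strings
#'
#' The shipped, versioned query set covering 17 desorption/ionization
#' technique searches (APCI, EI, ESI, DART, DIOS, FAB, LDI, NALDI, MALDI,
#' MALDI restricted to small molecules, NIMS and its imaging/initiator
#' variants, SALDI, SELDI, SIMS and SIMS imaging). Each raw query is
#' conjoined with the mass-spectrometry guard
#' `(METHODS:"mass spectrometry" OR METHODS:"MS")`.
#'
#' @return Named character vector of raw query strings (without the guard).
#' @export
technique_query_strings <- function() {
  path <- system.file("extdata", "technique_queries.tsv",
                      package = "lditrends", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  stats::setNames(tab$query, tab$shorthand)
}

#' Parsed technique query set
#'
#' @param guard Guard query string AND-ed onto every technique query; set to
#'   `NULL` to obtain the raw queries.
#' @return Named list of `ldi_query` nodes, one per technique shorthand.
#' @export
technique_queries <- function(
    guard = '(METHODS:"mass spectrometry" OR METHODS:"MS")') {
  raw <- technique_query_strings()
  guard_node <- if (is.null(guard)) NULL else parse_query(guard)
  lapply(raw, function(qs) {
    node <- parse_query(qs)
    if (is.null(guard_node)) node else query_and(node, guard_node)
  })
}
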