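# Boolean keyword-query language: expression tree, parser, serializer,
# evaluator. Queries are matched against whole tokens produced by tokenize();
# matching is case-insensitive (queries are casefolded at parse time) and
# accent-preserving, so the French "où" never matches "ou".

#' Boolean query expression nodes
#'
#' A query is a tree of nodes of kind `term`, `phrase`, `and`, `or` or `not`.
#' `term` matches a single whole token (optionally as a prefix when built with
#' a trailing `*` wildcard); `phrase` matches a consecutive token run; the
#' connectives have the usual semantics. `not` has exactly one child,
#' `and`/`or` at least two, leaves none.
#'
#' @param term Single token (character scalar), already lowercase.
#' @param wildcard Logical; `TRUE` for prefix matching (`vaccin*`).
#' @param tokens Character vector of two or more phrase tokens.
#' @param ... Two or more child `bq_expr` nodes.
#' @param x A single child `bq_expr` node.
#' @return A `bq_expr` object.
#' @name bq_expr
#' @examples
#' q <- bq_and(bq_term("covid"), bq_or(bq_term("vaccine"), bq_term("jab")))
#' eval_query(q, c("covid", "vaccine", "rollout"))
NULL

new_bq <- function(kind, term = NULL, wildcard = FALSE, tokens = NULL,
                   children = list()) {
  structure(
    list(kind = kind, term = term, wildcard = wildcard, tokens = tokens,
         children = children),
    class = "bq_expr"
  )
}

#' @rdname bq_expr
#' @export
bq_term <- function(term, wildcard = FALSE) {
  stopifnot(is.character(term), length(term) == 1, nzchar(term))
  new_bq("term", term = term, wildcard = isTRUE(wildcard))
}

#' @rdname bq_expr
#' @export
bq_phrase <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1, all(nzchar(tokens)))
  new_bq("phrase", tokens = tokens)
}

#' @rdname bq_expr
#' @export
bq_and <- function(...) {
  children <- list(...)
  if (length(children) == 1 && is.list(children[[1]]) &&
      !inherits(children[[1]], "bq_expr")) {
    children <- children[[1]]
  }
  stopifnot(length(children) >= 2)
  new_bq("and", children = children)
}

#' @rdname bq_expr
#' @export
bq_or <- function(...) {
  children <- list(...)
  if (length(children) == 1 && is.list(children[[1]]) &&
      !inherits(children[[1]], "bq_expr")) {
    children <- children[[1]]
  }
  stopifnot(length(children) >= 2)
  new_bq("or", children = children)
}

#' @rdname bq_expr
#' @export
bq_not <- function(x) {
  stopifnot(inherits(x, "bq_expr"))
  new_bq("not", children = list(x))
}

#' @export
print.bq_expr <- function(x, ...) {
  cat("<query> ", deparse_query(x), "\n", sep = "")
  invisible(x)
}

# ---- lexer -------------------------------------------------------------

# Token types: lparen, rparen, phrase, word, and, or, not.
# Operators are recognized in UPPERCASE only, so the lowercase stopwords
# "and" / "or" remain usable as baseline-query terms.
lex_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar(text)
  out <- list()
  pos <- 1
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) {
      pos <- pos + 1
    } else if (ch == "(") {
      out[[length(out) + 1]] <- list(type = "lparen", value = "(", pos = pos)
      pos <- pos + 1
    } else if (ch == ")") {
      out[[length(out) + 1]] <- list(type = "rparen", value = ")", pos = pos)
      pos <- pos + 1
    } else if (ch == "\"") {
      rest <- substr(text, pos + 1, n)
      close <- stringr::str_locate(rest, "\"")[1, 1]
      if (is.na(close)) {
        abort(sprintf("query syntax error at position %d: unbalanced quote", pos))
      }
      out[[length(out) + 1]] <- list(
        type = "phrase", value = substr(rest, 1, close - 1), pos = pos
      )
      pos <- pos + close + 1
    } else {
      word <- stringr::str_extract(substr(text, pos, n), "^[^\\s()\"]+")
      type <- switch(word, AND = "and", OR = "or", NOT = "not", "word")
      out[[length(out) + 1]] <- list(type = type, value = word, pos = pos)
      pos <- pos + nchar(word)
    }
  }
  out
}

# ---- parser ------------------------------------------------------------

#' Parse a Boolean keyword query
#'
#' Grammar: quoted phrases, bare terms, `AND`, `OR`, unary prefix `NOT`, and
#' parentheses. `AND` binds tighter than `OR`; adjacency (juxtaposition) is an
#' implicit `AND`, as in `covid AND (vaccine OR jab) NOT influenza`. A bare
#' term may carry a trailing `*` for prefix matching. Terms and phrases are
#' casefolded; accents are preserved. A quoted phrase of a single token parses
#' to a plain term.
#'
#' @param text Query string (non-empty).
#' @return A [bq_expr] tree.
#' @export
#' @examples
#' parse_query('covid AND (vaccine OR vaccination) NOT influenza')
#' parse_query('"long covid"')
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    abort("query text must be a non-empty string")
  }
  toks <- lex_query(text)
  if (length(toks) == 0) abort("query text must be a non-empty string")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() {
    tk <- st$toks[[st$i]]
    st$i <- st$i + 1
    tk
  }
  fail <- function(tk, what) {
    pos <- if (is.null(tk)) nchar(text) + 1 else tk$pos
    abort(sprintf("query syntax error at position %d: %s", pos, what))
  }

  p_primary <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "unexpected end of query")
    if (tk$type == "lparen") {
      advance()
      e <- p_or()
      cl <- peek()
      if (is.null(cl) || cl$type != "rparen") fail(cl, "expected ')'")
      advance()
      return(e)
    }
    if (tk$type == "phrase") {
      advance()
      ptoks <- tokenize(tk$value)
      if (length(ptoks) == 0) fail(tk, "empty phrase")
      if (length(ptoks) == 1) return(bq_term(ptoks))
      return(bq_phrase(ptoks))
    }
    if (tk$type == "word") {
      advance()
      w <- stringr::str_to_lower(tk$value)
      wildcard <- stringr::str_ends(w, stringr::fixed("*"))
      if (wildcard) w <- stringr::str_sub(w, 1, -2)
      if (!nzchar(w)) fail(tk, "bare '*' is not a term")
      if (stringr::str_detect(w, stringr::fixed("*"))) {
        fail(tk, "wildcard '*' is only allowed at the end of a term")
      }
      return(bq_term(w, wildcard = wildcard))
    }
    fail(tk, sprintf("unexpected '%s'", tk$value))
  }

  p_unary <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "not") {
      advance()
      return(bq_not(p_unary()))
    }
    p_primary()
  }

  p_and <- function() {
    parts <- list(p_unary())
    repeat {
      tk <- peek()
      if (is.null(tk)) break
      if (tk$type == "and") {
        advance()
        parts[[length(parts) + 1]] <- p_unary()
      } else if (tk$type %in% c("word", "phrase", "not", "lparen")) {
        # juxtaposition is an implicit AND
        parts[[length(parts) + 1]] <- p_unary()
      } else {
        break
      }
    }
    if (length(parts) == 1) parts[[1]] else bq_and(parts)
  }

  p_or <- function() {
    parts <- list(p_and())
    repeat {
      tk <- peek()
      if (is.null(tk) || tk$type != "or") break
      advance()
      parts[[length(parts) + 1]] <- p_and()
    }
    if (length(parts) == 1) parts[[1]] else bq_or(parts)
  }

  e <- p_or()
  leftover <- peek()
  if (!is.null(leftover)) fail(leftover, sprintf("unexpected '%s'", leftover$value))
  e
}

# ---- serializer --------------------------------------------------------

bq_prec <- function(kind) {
  switch(kind, or = 1, and = 2, not = 3, term = 4, phrase = 4)
}

#' Serialize a query expression back to query-string form
#'
#' Parentheses are emitted wherever needed so that
#' `parse_query(deparse_query(e))` is structurally identical to `e`.
#'
#' @param expr A [bq_expr].
#' @return A single query string.
#' @export
deparse_query <- function(expr) {
  stopifnot(inherits(expr, "bq_expr"))
  wrap <- function(child, self_prec, strict) {
    s <- deparse_query(child)
    p <- bq_prec(child$kind)
    need <- if (strict) p <= self_prec else p < self_prec
    if (need) paste0("(", s, ")") else s
  }
  switch(expr$kind,
    term = paste0(expr$term, if (expr$wildcard) "*" else ""),
    phrase = paste0("\"", paste(expr$tokens, collapse = " "), "\""),
    # strict wrapping keeps nested same-kind nodes from flattening on re-parse
    and = paste(vapply(expr$children, wrap, character(1),
                       self_prec = 2, strict = TRUE), collapse = " AND "),
    or = paste(vapply(expr$children, wrap, character(1),
                      self_prec = 1, strict = TRUE), collapse = " OR "),
    not = paste0("NOT ", wrap(expr$children[[1]], 3, strict = FALSE))
  )
}

# ---- evaluator ---------------------------------------------------------

phrase_at <- function(phrase, tokens) {
  k <- length(phrase)
  n <- length(tokens)
  if (k == 0 || n < k) return(FALSE)
  starts <- which(tokens == phrase[[1]])
  starts <- starts[starts + k - 1 <= n]
  for (i in starts) {
    if (all(tokens[i:(i + k - 1)] == phrase)) return(TRUE)
  }
  FALSE
}

#' Evaluate a query against a tokenized document
#'
#' A `term` is true iff the token is present (prefix match for wildcard
#' terms); a `phrase` is true iff its tokens occur consecutively; `and`, `or`
#' and `not` have standard Boolean semantics. An empty token vector makes
#' every leaf false. Evaluation is deterministic.
#'
#' @param expr A [bq_expr], or a query string (parsed on the fly).
#' @param tokens Character vector from [tokenize()].
#' @return Logical scalar.
#' @export
#' @examples
#' eval_query('"long covid"', tokenize("has long covid"))
eval_query <- function(expr, tokens) {
  if (is.character(expr)) expr <- parse_query(expr)
  stopifnot(inherits(expr, "bq_expr"), is.character(tokens))
  switch(expr$kind,
    term = if (expr$wildcard) {
      length(tokens) > 0 && any(startsWith(tokens, expr$term))
    } else {
      expr$term %in% tokens
    },
    phrase = phrase_at(expr$tokens, tokens),
    and = all(vapply(expr$children, eval_query, logical(1), tokens = tokens)),
    or = any(vapply(expr$children, eval_query, logical(1), tokens = tokens)),
    not = !eval_query(expr$children[[1]], tokens)
  )
}
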