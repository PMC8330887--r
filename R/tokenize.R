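# Tokenization and the two post-level auxiliary queries: the interrogative
# (question) detector and the common-word baseline.

#' Tokenize post text
#'
#' Casefolds, keeps `?` as a sentinel token, splits French apostrophe elisions
#' so the clitic keeps its apostrophe (`"l'immunité"` -> `l'`, `immunité`),
#' strips punctuation except intra-word hyphens, and preserves accents.
#'
#' @param text Character vector of raw post text.
#' @param language Language tag (`"en"` or `"fr"`); the rules are shared, the
#'   argument is kept for interface stability.
#' @return For a single string, a character vector of tokens; for a vector of
#'   strings, a list of token vectors. Empty text gives zero tokens.
#' @export
#' @examples
#' tokenize("Covid-19 vaccines?")
#' tokenize("L'immunité collective")
tokenize <- function(text, language = "en") {
  if (length(text) == 0) return(list())
  x <- stringr::str_to_lower(as.character(text))
  x <- stringr::str_replace_all(x, "’", "'")     # typographic apostrophe
  x <- stringr::str_replace_all(x, "\\?", " ? ")
  # French elision: clitic keeps its apostrophe and separates from the host
  x <- stringr::str_replace_all(x, "\\b(qu|[ldjcnsmt])'", "\\1' ")
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}'?-]+", " ")
  toks <- stringr::str_split(stringr::str_squish(x), stringr::fixed(" "))
  toks <- lapply(toks, function(tk) {
    tk <- stringr::str_replace_all(tk, "^[-]+|[-]+$", "")
    tk[nzchar(tk)]
  })
  if (length(text) == 1) toks[[1]] else toks
}

#' Build the interrogative (question) query for a language
#'
#' Reproduces the question search string paired with every taxonomy search:
#' a post is a question if it contains a literal `?`, an interrogative word,
#' an interrogative phrase (French `est-ce que`), an auxiliary-subject
#' inversion (`are they`, sentence-initial `do`), or a French hyphenated
#' inversion form (`peut-on`).
#'
#' @param language `"en"` or `"fr"`.
#' @return A `question_query` object.
#' @export
#' @examples
#' qq <- build_question_query("en")
#' detect_question(tokenize("why is it spreading"), qq)
build_question_query <- function(language) {
  if (identical(language, "en")) {
    q <- list(
      language = "en",
      lexicon = c("what", "why", "how", "when", "where", "who", "whom",
                  "whose", "which"),
      phrases = list(),
      aux = c("do", "does", "did", "can", "could", "should", "would", "will",
              "is", "are", "was", "were", "am", "has", "have"),
      pronouns = c("i", "you", "he", "she", "it", "we", "they", "there",
                   "this", "that", "anyone", "anybody"),
      hyphen_pattern = NULL
    )
  } else if (identical(language, "fr")) {
    q <- list(
      language = "fr",
      lexicon = c("pourquoi", "comment", "quand", "où", "qui", "quoi",
                  "combien", "quel", "quelle", "quels", "quelles"),
      phrases = list(c("est-ce", "que"), c("est-ce", "qu'")),
      aux = character(0),
      pronouns = character(0),
      hyphen_pattern = "-(je|tu|il|elle|on|nous|vous|ils|elles|ce)$"
    )
  } else {
    abort(sprintf("unsupported language '%s' (supported: en, fr)", language))
  }
  structure(q, class = "question_query")
}

#' Detect whether a tokenized post poses a question
#'
#' @param tokens Character vector from [tokenize()].
#' @param question_query A [build_question_query()] object.
#' @return Logical scalar.
#' @export
detect_question <- function(tokens, question_query) {
  stopifnot(inherits(question_query, "question_query"))
  if (length(tokens) == 0) return(FALSE)
  if ("?" %in% tokens) return(TRUE)
  if (any(tokens %in% question_query$lexicon)) return(TRUE)
  for (ph in question_query$phrases) {
    if (phrase_at(ph, tokens)) return(TRUE)
  }
  if (length(question_query$aux) > 0) {
    if (tokens[[1]] %in% question_query$aux) return(TRUE)
    idx <- which(tokens %in% question_query$aux)
    idx <- idx[idx < length(tokens)]
    if (length(idx) > 0 && any(tokens[idx + 1] %in% question_query$pronouns)) {
      return(TRUE)
    }
  }
  if (!is.null(question_query$hyphen_pattern) &&
      any(stringr::str_detect(tokens, question_query$hyphen_pattern))) {
    return(TRUE)
  }
  FALSE
}

#' Common-word baseline query
#'
#' The total size of the online conversation is estimated from posts that
#' mention at least one of the most common function words of the language
#' (English *the, and, or, I*; French *le, la, ou, et*). Accents matter:
#' "où" is an interrogative, "ou" a baseline conjunction.
#'
#' @param language `"en"` or `"fr"`.
#' @param words Optional custom common-word set (non-empty).
#' @return A `baseline_query` object with a `words` element.
#' @export
build_baseline_query <- function(language, words = NULL) {
  defaults <- list(
    en = c("the", "and", "or", "i", "a", "to", "of", "in", "it", "is"),
    fr = c("le", "la", "les", "et", "ou", "un", "une", "de", "je", "est")
  )
  if (is.null(words)) {
    if (!language %in% names(defaults)) {
      abort(sprintf("unsupported language '%s' (supported: en, fr)", language))
    }
    words <- defaults[[language]]
  }
  stopifnot(is.character(words), length(words) > 0)
  structure(list(language = language, words = words), class = "baseline_query")
}

#' @rdname build_baseline_query
#' @param tokens Character vector from [tokenize()].
#' @export
in_baseline <- function(tokens, baseline_query) {
  stopifnot(inherits(baseline_query, "baseline_query"))
  any(tokens %in% baseline_query$words)
}
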