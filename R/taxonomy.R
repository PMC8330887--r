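# The social-listening taxonomy: ordered top-level categories, keyword-defined
# subcategories with one Boolean search string per language, plus the
# language-level question and baseline queries.

#' Construct a taxonomy
#'
#' @param categories Ordered character vector of top-level category names.
#' @param subcategories A data frame with columns `id` (unique slug),
#'   `category` (member of `categories`), `name` (display name), and one
#'   `query_<lang>` column per language holding Boolean query strings.
#' @param languages Language tags covered by the query columns (default taken
#'   from the `query_*` columns present).
#' @param baseline_words Optional named list of per-language common-word sets;
#'   defaults from [build_baseline_query()].
#' @param expected_categories,expected_subcategories Optional declared counts;
#'   a mismatch with the actual table is an error.
#' @return A `taxonomy` object.
#' @export
taxonomy <- function(categories, subcategories, languages = NULL,
                     baseline_words = NULL,
                     expected_categories = NULL,
                     expected_subcategories = NULL) {
  subcategories <- as_tibble(subcategories)
  qcols <- grep("^query_", names(subcategories), value = TRUE)
  if (is.null(languages)) languages <- sub("^query_", "", qcols)
  if (length(languages) == 0) abort("taxonomy needs at least one query_<lang> column")
  missing_cols <- setdiff(c("id", "category", "name", paste0("query_", languages)),
                          names(subcategories))
  if (length(missing_cols) > 0) {
    abort(paste0("subcategories is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- subcategories$id[duplicated(subcategories$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate subcategory id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_cat <- setdiff(unique(subcategories$category), categories)
  if (length(bad_cat) > 0) {
    abort(paste0("subcategory category not in declared categories: ",
                 paste(bad_cat, collapse = ", ")))
  }
  if (!is.null(expected_categories) &&
      length(categories) != expected_categories) {
    abort(sprintf("taxonomy declares %d categories but lists %d",
                  expected_categories, length(categories)))
  }
  if (!is.null(expected_subcategories) &&
      nrow(subcategories) != expected_subcategories) {
    abort(sprintf("taxonomy declares %d subcategories but lists %d",
                  expected_subcategories, nrow(subcategories)))
  }

  queries <- lapply(seq_len(nrow(subcategories)), function(i) {
    out <- list()
    for (lang in languages) {
      qs <- subcategories[[paste0("query_", lang)]][[i]]
      out[[lang]] <- tryCatch(
        parse_query(qs),
        error = function(e) {
          abort(sprintf("query for subcategory '%s' (%s) failed to parse: %s",
                        subcategories$id[[i]], lang, conditionMessage(e)))
        }
      )
    }
    out
  })
  names(queries) <- subcategories$id

  question <- lapply(setNames(languages, languages), build_question_query)
  baseline <- lapply(setNames(languages, languages), function(lang) {
    build_baseline_query(lang, words = baseline_words[[lang]])
  })

  structure(
    list(categories = categories, subcategories = subcategories,
         languages = languages, queries = queries,
         question = question, baseline = baseline),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d categories, %d subcategories, languages: %s\n",
              length(x$categories), nrow(x$subcategories),
              paste(x$languages, collapse = ", ")))
  invisible(x)
}

#' Load a taxonomy definition file
#'
#' Reads a YAML (or JSON) taxonomy document with top-level keys `categories`,
#' `subcategories` (each `{id, category, name, query: {<lang>: "..."}}`),
#' optional `baseline_words: {<lang>: [...]}`, and optional declared counts
#' `expected_categories` / `expected_subcategories`. All query strings are
#' parsed at load time; a parse failure names the offending subcategory, and
#' duplicate ids or count mismatches are errors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [taxonomy] object.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("taxonomy file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$categories) || is.null(doc$subcategories)) {
    abort("taxonomy file must declare 'categories' and 'subcategories'")
  }
  categories <- unlist(doc$categories, use.names = FALSE)
  langs <- unique(unlist(lapply(doc$subcategories, function(s) names(s$query))))
  rows <- lapply(doc$subcategories, function(s) {
    if (is.null(s$id) || is.null(s$category) || is.null(s$query)) {
      abort("each subcategory needs 'id', 'category' and 'query' fields")
    }
    row <- tibble(id = s$id, category = s$category, name = s$name %||% s$id)
    for (lang in langs) {
      if (is.null(s$query[[lang]])) {
        abort(sprintf("subcategory '%s' has no %s query", s$id, lang))
      }
      row[[paste0("query_", lang)]] <- s$query[[lang]]
    }
    row
  })
  taxonomy(
    categories = categories,
    subcategories = dplyr::bind_rows(rows),
    languages = langs,
    baseline_words = doc$baseline_words,
    expected_categories = doc$expected_categories,
    expected_subcategories = doc$expected_subcategories
  )
}

#' Write a taxonomy to a YAML definition file
#'
#' Inverse of [load_taxonomy()]: query trees are serialized back to query
#' strings with [deparse_query()] and declared counts are included.
#'
#' @param tax A [taxonomy] object.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  subs <- lapply(seq_len(nrow(tax$subcategories)), function(i) {
    s <- tax$subcategories[i, ]
    list(
      id = s$id, category = s$category, name = s$name,
      query = lapply(setNames(tax$languages, tax$languages), function(lang) {
        deparse_query(tax$queries[[s$id]][[lang]])
      })
    )
  })
  doc <- list(
    expected_categories = length(tax$categories),
    expected_subcategories = nrow(tax$subcategories),
    categories = as.list(tax$categories),
    subcategories = subs,
    baseline_words = lapply(tax$baseline, function(b) as.list(b$words))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
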