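# Classification: pair every post with every taxonomy subcategory search,
# the question query and the common-word baseline.

classification_columns <- c("post_id", "language", "platform", "week",
                            "week_start", "matched", "n_matched",
                            "is_question", "in_baseline", "engagement_total")

#' Classify a single post against a taxonomy
#'
#' A post matches every subcategory whose Boolean search string evaluates
#' true on its tokens (multi-label matching is expected: online narratives
#' overlap across categories). A post counts at most once per subcategory,
#' regardless of how many keywords hit. The question and baseline queries are
#' evaluated on the same tokens.
#'
#' @param post A single-row post tibble (or a list with the same fields).
#' @param taxonomy A [taxonomy] object.
#' @return A one-row classification tibble with list-column `matched`.
#' @export
#' @examples
#' fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 3)
#' p <- posts_tibble("p1", "do covid t01alpha doses work?", "en",
#'                   "2020-03-23T12:00:00Z", "twitter", likes = 3)
#' classify_post(p, fix$taxonomy)
classify_post <- function(post, taxonomy) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  post <- as_tibble(as.list(post))
  classify_corpus(post, taxonomy, warn_unsupported = TRUE)$records
}

#' Classify a corpus of posts
#'
#' Runs every post through [tokenize()], evaluates all subcategory searches
#' for the post's language, the question query and the baseline query, and
#' returns per-post records plus summary counts. Posts in a language the
#' taxonomy does not cover get an empty match set (with one warning).
#'
#' @param posts A post tibble ([posts_tibble()] / [read_posts()]).
#' @param taxonomy A [taxonomy] object.
#' @param warn_unsupported Warn when posts carry unsupported language tags.
#' @return A list with `records` (one row per post: `post_id`, `language`,
#'   `platform`, `week`, `week_start`, list-column `matched`, `n_matched`,
#'   `is_question`, `in_baseline`, `engagement_total`) and `summary` (totals
#'   per subcategory, question and baseline totals, platform shares).
#' @export
classify_corpus <- function(posts, taxonomy, warn_unsupported = TRUE) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  posts <- as_tibble(posts)
  n <- nrow(posts)
  ids <- taxonomy$subcategories$id

  if (n == 0) {
    records <- tibble(
      post_id = character(0), language = character(0),
      platform = character(0), week = character(0),
      week_start = as.Date(character(0)), matched = list(),
      n_matched = integer(0), is_question = logical(0),
      in_baseline = logical(0), engagement_total = integer(0)
    )
    return(list(records = records,
                summary = summarize_classification(records, taxonomy)))
  }

  toks <- tokenize(posts$text)
  if (n == 1) toks <- list(toks)

  # per-language compiled query list, in taxonomy order
  lang_queries <- lapply(setNames(taxonomy$languages, taxonomy$languages),
                         function(lang) {
                           lapply(taxonomy$queries, function(q) q[[lang]])
                         })

  unsupported <- setdiff(unique(posts$language), taxonomy$languages)
  if (length(unsupported) > 0 && warn_unsupported) {
    warn(sprintf("posts in unsupported language(s) %s matched nothing",
                 paste(unsupported, collapse = ", ")))
  }

  matched <- vector("list", n)
  is_question <- logical(n)
  in_base <- logical(n)
  for (i in seq_len(n)) {
    lang <- posts$language[[i]]
    tk <- toks[[i]]
    if (!lang %in% taxonomy$languages) {
      matched[[i]] <- character(0)
      next
    }
    hits <- vapply(lang_queries[[lang]], eval_query, logical(1), tokens = tk)
    matched[[i]] <- ids[hits]
    is_question[[i]] <- detect_question(tk, taxonomy$question[[lang]])
    in_base[[i]] <- in_baseline(tk, taxonomy$baseline[[lang]])
  }

  records <- tibble(
    post_id = posts$id,
    language = posts$language,
    platform = posts$platform,
    week = iso_week_key(posts$timestamp),
    week_start = week_monday(posts$timestamp),
    matched = matched,
    n_matched = lengths(matched),
    is_question = is_question,
    in_baseline = in_base,
    engagement_total = rowSums(posts[, engagement_kinds, drop = FALSE])
  )
  records$engagement_total <- as.integer(records$engagement_total)
  list(records = records,
       summary = summarize_classification(records, taxonomy))
}

#' Summarize classification records
#'
#' @param records Classification records from [classify_corpus()].
#' @param taxonomy Optional [taxonomy]; when given, subcategories with zero
#'   matches are kept in the per-subcategory table.
#' @return A list: `n_posts`, `per_subcategory` (volume and question volume),
#'   `question_total`, `baseline_total`, `platform_shares`.
#' @export
summarize_classification <- function(records, taxonomy = NULL) {
  pairs <- match_pairs(records)
  per_sub <- pairs |>
    group_by(subcategory) |>
    summarise(volume = dplyr::n(),
              question_volume = sum(.data$is_question), .groups = "drop")
  if (!is.null(taxonomy)) {
    per_sub <- tibble(subcategory = taxonomy$subcategories$id) |>
      left_join(per_sub, by = "subcategory") |>
      mutate(volume = dplyr::coalesce(.data$volume, 0L),
             question_volume = dplyr::coalesce(.data$question_volume, 0L))
  }
  shares <- if (nrow(records) > 0) {
    records |>
      count(.data$platform, name = "posts") |>
      mutate(share = .data$posts / sum(.data$posts)) |>
      arrange(dplyr::desc(.data$share))
  } else {
    tibble(platform = character(0), posts = integer(0), share = numeric(0))
  }
  list(
    n_posts = nrow(records),
    per_subcategory = per_sub,
    question_total = sum(records$is_question),
    baseline_total = sum(records$in_baseline),
    platform_shares = shares
  )
}

#' Expand classification records into (post, subcategory) match pairs
#'
#' Posts with an empty match set contribute no rows; a multi-label post
#' contributes one row per matched subcategory.
#'
#' @param records Classification records from [classify_corpus()].
#' @return A tibble with `post_id`, `subcategory`, `week`, `week_start`,
#'   `is_question`, `engagement_total`.
#' @export
match_pairs <- function(records) {
  if (nrow(records) == 0 || sum(lengths(records$matched)) == 0) {
    return(tibble(post_id = character(0), week = character(0),
                  week_start = as.Date(character(0)),
                  subcategory = character(0), is_question = logical(0),
                  engagement_total = integer(0)))
  }
  records |>
    select("post_id", "week", "week_start", "matched",
           "is_question", "engagement_total") |>
    tidyr::unnest_longer("matched", values_to = "subcategory") |>
    filter(!is.na(.data$subcategory))
}
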