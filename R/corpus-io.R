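# Post-corpus I/O. A corpus is a tibble of posts; files are JSONL (one JSON
# object per line) or CSV, both UTF-8 and lossless round-trips.

#' Platforms and engagement kinds recognized in post records
#' @export
post_platforms <- c("twitter", "blog", "reddit", "message_board",
                    "news_comment", "review", "instagram", "facebook",
                    "youtube")

#' @rdname post_platforms
#' @export
engagement_kinds <- c("likes", "shares", "poll_votes", "reactions")

post_columns <- c("id", "text", "language", "timestamp", "platform",
                  engagement_kinds)

parse_timestamp <- function(x) {
  out <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  dateish <- is.na(out) & !is.na(x)
  if (any(dateish)) {
    d <- suppressWarnings(lubridate::ymd(x[dateish], quiet = TRUE))
    out[dateish] <- lubridate::as_datetime(d, tz = "UTC")
  }
  out
}

format_timestamp <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Build a validated post tibble
#'
#' @param id,text,language,timestamp,platform Field vectors; `timestamp` may
#'   be POSIXct or ISO-8601 strings (normalized to UTC).
#' @param likes,shares,poll_votes,reactions Non-negative engagement counts.
#' @return A tibble with one row per post.
#' @export
posts_tibble <- function(id, text, language, timestamp, platform,
                         likes = 0L, shares = 0L, poll_votes = 0L,
                         reactions = 0L) {
  if (!inherits(timestamp, "POSIXct")) timestamp <- parse_timestamp(timestamp)
  tibble(
    id = as.character(id), text = as.character(text),
    language = as.character(language),
    timestamp = lubridate::with_tz(timestamp, "UTC"),
    platform = as.character(platform),
    likes = as.integer(likes), shares = as.integer(shares),
    poll_votes = as.integer(poll_votes), reactions = as.integer(reactions)
  )
}

# Returns NA_character_ when valid, else a reason.
post_problem <- function(row) {
  if (is.na(row$id) || !nzchar(row$id)) return("missing id")
  if (is.na(row$text)) return("missing text")
  if (is.na(row$language) || !nzchar(row$language)) return("missing language")
  if (is.na(row$timestamp)) return("unparseable timestamp")
  if (is.na(row$platform) || !row$platform %in% post_platforms) {
    return("unknown platform")
  }
  eng <- unlist(row[engagement_kinds])
  if (anyNA(eng) || any(eng < 0)) return("negative or missing engagement count")
  NA_character_
}

validate_posts <- function(posts, strict, where) {
  problems <- vapply(seq_len(nrow(posts)), function(i) post_problem(posts[i, ]),
                     character(1))
  bad <- which(!is.na(problems))
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf("%s: invalid record at line %d: %s",
                    where, bad[[1]], problems[[bad[[1]]]]))
    }
    warn(sprintf("%s: skipped %d malformed record(s)", where, length(bad)))
    posts <- posts[-bad, ]
  }
  dup <- duplicated(posts$id, fromLast = TRUE)
  if (any(dup)) {
    if (strict) {
      abort(sprintf("%s: duplicate post id '%s'", where, posts$id[dup][[1]]))
    }
    warn(sprintf("%s: %d duplicate post id(s), keeping last occurrence",
                 where, sum(dup)))
    posts <- posts[!dup, ]
  }
  posts
}

#' Read a post corpus
#'
#' JSONL (one object per line) or CSV with columns
#' `id,text,language,timestamp,platform,likes,shares,poll_votes,reactions`.
#' Timestamps are normalized to UTC on read. In lenient mode (default)
#' malformed records are skipped with a warning and duplicate ids keep the
#' last occurrence; in strict mode the first problem aborts with its line.
#'
#' @param path Input file; format inferred from the extension unless given.
#' @param format `"auto"`, `"jsonl"` or `"csv"`.
#' @param strict Abort on the first malformed record instead of skipping.
#' @return A tibble of posts.
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv"),
                       strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "jsonl"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (nrow(raw) == 0) return(posts_tibble(character(0), character(0),
                                            character(0), character(0),
                                            character(0)))
    for (k in engagement_kinds) {
      if (!k %in% names(raw)) raw[[k]] <- "0"
    }
    posts <- posts_tibble(raw$id, raw$text, raw$language,
                          raw$timestamp, raw$platform,
                          suppressWarnings(as.integer(raw$likes)),
                          suppressWarnings(as.integer(raw$shares)),
                          suppressWarnings(as.integer(raw$poll_votes)),
                          suppressWarnings(as.integer(raw$reactions)))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(posts_tibble(character(0), character(0),
                                                character(0), character(0),
                                                character(0)))
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) {
        if (strict) abort(sprintf("%s: invalid JSON at line %d", path, i))
        rows[i] <- list(NULL)
        next
      }
      rows[[i]] <- tibble(
        id = as.character(rec$id %||% NA_character_),
        text = as.character(rec$text %||% NA_character_),
        language = as.character(rec$language %||% NA_character_),
        timestamp = as.character(rec$timestamp %||% NA_character_),
        platform = as.character(rec$platform %||% NA_character_),
        likes = as.integer(rec$likes %||% 0L),
        shares = as.integer(rec$shares %||% 0L),
        poll_votes = as.integer(rec$poll_votes %||% 0L),
        reactions = as.integer(rec$reactions %||% 0L)
      )
    }
    dropped <- sum(vapply(rows, is.null, logical(1)))
    if (dropped > 0) {
      warn(sprintf("%s: skipped %d unparseable line(s)", path, dropped))
    }
    raw <- dplyr::bind_rows(rows)
    posts <- posts_tibble(raw$id, raw$text, raw$language, raw$timestamp,
                          raw$platform, raw$likes, raw$shares,
                          raw$poll_votes, raw$reactions)
  }
  validate_posts(posts, strict = strict, where = path)
}

#' Write a post corpus
#'
#' @param posts A post tibble (see [posts_tibble()]).
#' @param path Output path; `.csv` writes CSV, anything else JSONL.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  posts <- as_tibble(posts)[, post_columns]
  if (tolower(tools::file_ext(path)) == "csv") {
    out <- posts
    out$timestamp <- format_timestamp(out$timestamp)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(posts)), function(i) {
      rec <- as.list(posts[i, ])
      rec$timestamp <- format_timestamp(rec$timestamp)
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read / write coded validation samples
#'
#' Coded samples record the human relevance coding used for retrieval
#' validation: one row per (post, coder) with the subcategory the post was
#' retrieved for (or `"not_retrieved"`) and a binary relevance code.
#'
#' @param path CSV with columns `id,subcategory,code,coder`.
#' @return A tibble of coded items; `code` is integer 0/1.
#' @export
read_coded <- function(path) {
  if (!file.exists(path)) abort(sprintf("coded file not found: %s", path))
  x <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), subcategory = readr::col_character(),
    code = readr::col_integer(), coder = readr::col_character()
  ), progress = FALSE)
  if (nrow(x) > 0 && (anyNA(x$code) || !all(x$code %in% c(0L, 1L)))) {
    abort(sprintf("%s: relevance codes must be 0 or 1", path))
  }
  x
}

#' @rdname read_coded
#' @param coded A coded-item tibble.
#' @export
write_coded <- function(coded, path) {
  coded <- as_tibble(coded)[, c("id", "subcategory", "code", "coder")]
  if (nrow(coded) > 0 && !all(coded$code %in% c(0L, 1L))) {
    abort("relevance codes must be 0 or 1")
  }
  readr::write_csv(coded, path, progress = FALSE)
  invisible(path)
}
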