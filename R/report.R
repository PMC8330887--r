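# Weekly-report rendering and the command layer behind the `infodemic` CLI
# script (inst/cli/infodemic.R). Each cmd_* function reads and writes files,
# returns the paths it wrote, and records a JSON run manifest so every
# artifact is regenerable bit-identically from (inputs, config, seed).

#' Run configuration for the pipeline commands
#'
#' @param taxonomy Path to a taxonomy definition file.
#' @param corpus Path(s) to post corpora (JSONL or CSV).
#' @param out_dir Output directory (created if missing).
#' @param since,until Optional date range filter (inclusive).
#' @param signals A [signal_config()].
#' @param strict Strict corpus reading (abort on first malformed record).
#' @param seed Integer seed recorded in the manifest and used by seeded
#'   steps.
#' @return A `run_config` list.
#' @export
run_config <- function(taxonomy = NULL, corpus = NULL, out_dir = ".",
                       since = NULL, until = NULL,
                       signals = signal_config(), strict = FALSE, seed = 1) {
  if (!is.null(since) && !is.null(until) &&
      lubridate::as_date(since) > lubridate::as_date(until)) {
    abort("empty date range: since is after until")
  }
  structure(list(taxonomy = taxonomy, corpus = corpus, out_dir = out_dir,
                 since = since, until = until, signals = signals,
                 strict = strict, seed = seed),
            class = "run_config")
}

write_manifest <- function(config, path, inputs, outputs) {
  # record file names, not absolute paths, so reruns in different
  # directories produce bit-identical manifests
  strip_dirs <- function(x) {
    rapply(x, function(v) {
      if (is.character(v)) basename(v) else v
    }, how = "replace")
  }
  inputs <- strip_dirs(inputs)
  outputs <- strip_dirs(outputs)
  manifest <- list(
    package = "infodemic",
    version = as.character(utils::packageVersion("infodemic")),
    seed = config$seed,
    config = list(
      since = config$since, until = config$until, strict = config$strict,
      signal_thresholds = unclass(config$signals)
    ),
    inputs = inputs,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

filter_range <- function(posts, config) {
  if (!is.null(config$since)) {
    posts <- posts[lubridate::as_date(posts$timestamp) >=
                     lubridate::as_date(config$since), ]
  }
  if (!is.null(config$until)) {
    posts <- posts[lubridate::as_date(posts$timestamp) <=
                     lubridate::as_date(config$until), ]
  }
  posts
}

#' Read / write classification records
#'
#' Records round-trip through CSV; the multi-label `matched` set is joined
#' with `|` (empty string for no matches).
#'
#' @param records Classification records from [classify_corpus()].
#' @param path CSV path.
#' @return The records tibble / `path` invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  out$matched <- vapply(records$matched, paste, character(1), collapse = "|")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    post_id = readr::col_character(), language = readr::col_character(),
    platform = readr::col_character(), week = readr::col_character(),
    week_start = readr::col_date(), matched = readr::col_character(),
    n_matched = readr::col_integer(), is_question = readr::col_logical(),
    in_baseline = readr::col_logical(),
    engagement_total = readr::col_integer()
  ), progress = FALSE)
  x$matched[is.na(x$matched)] <- ""
  x$matched <- lapply(strsplit(x$matched, "|", fixed = TRUE),
                      function(m) m[nzchar(m)])
  x
}

#' Render the weekly signal report as Markdown
#'
#' Mirrors the structure of a weekly written report: the review week, the
#' thresholds used, and one section per flagged topic with the evidence
#' that triggered it (volume, velocity, question share, engagement).
#'
#' @param flags Signal flags from [detect_signals()].
#' @param stats Weekly statistics from [weekly_aggregate()].
#' @param week Week key the report covers.
#' @param config A [signal_config()].
#' @return Character vector of Markdown lines.
#' @export
render_weekly_report <- function(flags, stats, week, config = signal_config()) {
  fmt_pct <- function(x) {
    ifelse(is.na(x), "undefined", sprintf("%+.1f%%", x))
  }
  lines <- c(
    sprintf("# Weekly infodemic signal report - %s", week),
    "",
    sprintf(paste0("Flagging thresholds: velocity >= %+.0f%%, question share > ",
                   "%.0fth percentile, engagement > %.0fth percentile, ",
                   "up to %d topics."),
            config$velocity_threshold_pct,
            100 * config$question_share_quantile,
            100 * config$engagement_quantile, config$max_topics),
    ""
  )
  wk <- stats[stats$week == week, ]
  lines <- c(lines,
             sprintf("Topics tracked: %d; total weekly volume: %d posts.",
                     nrow(wk), sum(wk$volume)), "")
  if (nrow(flags) == 0) {
    return(c(lines, "No potential information voids flagged this week."))
  }
  lines <- c(lines, sprintf("## Flagged topics (%d)", nrow(flags)), "")
  for (i in seq_len(nrow(flags))) {
    f <- flags[i, ]
    lines <- c(lines,
      sprintf("### %d. %s", i, f$subcategory),
      sprintf("- triggers: %s", paste(f$triggers[[1]], collapse = ", ")),
      sprintf("- volume: %d posts (%d questions, share %s)", f$volume,
              f$question_volume,
              ifelse(is.na(f$question_share), "undefined",
                     sprintf("%.0f%%", 100 * f$question_share))),
      sprintf("- velocity: %s", fmt_pct(f$velocity)),
      sprintf("- engagement: %d interactions", f$engagement_total),
      "")
  }
  lines
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Pipeline commands
#'
#' File-level entry points tying the modules into the weekly workflow; the
#' `infodemic` CLI script is a thin argument-parsing wrapper around them.
#' `cmd_synth()` writes a synthetic corpus + taxonomy + ground truth;
#' `cmd_classify()` classifies a corpus against a taxonomy;
#' `cmd_aggregate()` turns records into weekly statistics;
#' `cmd_signals()` flags potential information voids for a week;
#' `cmd_validate()` computes the validation metrics from a coded sample;
#' `cmd_report()` renders the Markdown weekly report. Every command writes a
#' `*_manifest.json` recording inputs, config and seed.
#'
#' @param config A [run_config()].
#' @param week Week key (`"2020-W16"`) for `cmd_signals` / `cmd_report`;
#'   default: last week in the statistics.
#' @return Named character vector of written paths, invisibly.
#' @name pipeline_commands
NULL

#' @rdname pipeline_commands
#' @param spec A [corpus_spec()] for `cmd_synth`.
#' @export
cmd_synth <- function(spec, config) {
  dir <- ensure_dir(config$out_dir)
  corpus <- generate_corpus(spec)
  paths <- c(
    corpus = file.path(dir, "corpus.jsonl"),
    taxonomy = file.path(dir, "taxonomy.yaml"),
    truth = file.path(dir, "ground_truth.csv"),
    manifest = file.path(dir, "synth_manifest.json")
  )
  write_posts(corpus$posts, paths[["corpus"]])
  write_taxonomy(corpus$fixture$taxonomy, paths[["taxonomy"]])
  readr::write_csv(corpus$truth, paths[["truth"]], progress = FALSE)
  write_manifest(config, paths[["manifest"]],
                 inputs = list(seed = spec$seed, weeks = spec$weeks,
                               topics = nrow(spec$fixture$taxonomy$subcategories)),
                 outputs = as.list(paths[names(paths) != "manifest"]))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @export
cmd_classify <- function(config) {
  if (is.null(config$taxonomy) || !file.exists(config$taxonomy)) {
    abort("taxonomy file is required", class = "infodemic_usage_error")
  }
  if (is.null(config$corpus) || !all(file.exists(config$corpus))) {
    abort("corpus file(s) required", class = "infodemic_usage_error")
  }
  dir <- ensure_dir(config$out_dir)
  tax <- load_taxonomy(config$taxonomy)
  posts <- dplyr::bind_rows(lapply(config$corpus, read_posts,
                                   strict = config$strict))
  posts <- filter_range(posts, config)
  res <- classify_corpus(posts, tax)
  paths <- c(records = file.path(dir, "records.csv"),
             summary = file.path(dir, "classification_summary.json"),
             manifest = file.path(dir, "classify_manifest.json"))
  write_records(res$records, paths[["records"]])
  s <- res$summary
  jsonlite::write_json(
    list(n_posts = s$n_posts, question_total = s$question_total,
         baseline_total = s$baseline_total,
         per_subcategory = s$per_subcategory,
         platform_shares = s$platform_shares),
    paths[["summary"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, paths[["manifest"]],
                 inputs = list(taxonomy = config$taxonomy,
                               corpus = as.list(config$corpus)),
                 outputs = as.list(paths[names(paths) != "manifest"]))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @param records_path Path to a records CSV from `cmd_classify`.
#' @export
cmd_aggregate <- function(records_path, config) {
  if (!file.exists(records_path)) {
    abort("records file is required", class = "infodemic_usage_error")
  }
  dir <- ensure_dir(config$out_dir)
  records <- read_records(records_path)
  subcats <- NULL
  if (!is.null(config$taxonomy) && file.exists(config$taxonomy)) {
    subcats <- load_taxonomy(config$taxonomy)$subcategories$id
  }
  stats <- weekly_aggregate(records, subcategories = subcats)
  paths <- c(stats = file.path(dir, "weekly_stats.csv"),
             manifest = file.path(dir, "aggregate_manifest.json"))
  readr::write_csv(stats, paths[["stats"]], progress = FALSE)
  write_manifest(config, paths[["manifest"]],
                 inputs = list(records = records_path),
                 outputs = as.list(paths["stats"]))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @param stats_path Path to a weekly statistics CSV from `cmd_aggregate`.
#' @export
cmd_signals <- function(stats_path, config, week = NULL) {
  if (!file.exists(stats_path)) {
    abort("weekly stats file is required", class = "infodemic_usage_error")
  }
  dir <- ensure_dir(config$out_dir)
  stats <- readr::read_csv(stats_path, col_types = readr::cols(),
                           progress = FALSE)
  week <- week %||% max(stats$week)
  flags <- detect_signals(stats, week, config$signals)
  paths <- c(signals = file.path(dir, "signals.json"),
             manifest = file.path(dir, "signals_manifest.json"))
  out <- flags
  out$triggers <- lapply(out$triggers, identity)
  jsonlite::write_json(
    list(week = week, thresholds = unclass(config$signals), flags = out),
    paths[["signals"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, paths[["manifest"]],
                 inputs = list(stats = stats_path, week = week),
                 outputs = as.list(paths["signals"]))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @param coded_path Coded-sample CSV (`id,subcategory,code,coder`) where
#'   subcategory `"not_retrieved"` marks the recall sample.
#' @export
cmd_validate <- function(coded_path, config) {
  if (!file.exists(coded_path)) {
    abort("coded sample file is required", class = "infodemic_usage_error")
  }
  dir <- ensure_dir(config$out_dir)
  coded <- read_coded(coded_path)
  first_coder <- coded |>
    filter(.data$coder == dplyr::first(.data$coder))
  retrieved <- first_coder |> filter(.data$subcategory != "not_retrieved")
  not_retrieved <- first_coder |> filter(.data$subcategory == "not_retrieved")
  if (nrow(retrieved) == 0 || nrow(not_retrieved) == 0) {
    abort("need both retrieved and not_retrieved coded items")
  }
  conf <- confusion_counts(
    tp = sum(retrieved$code == 1), fp = sum(retrieved$code == 0),
    fn = sum(not_retrieved$code == 1), tn = sum(not_retrieved$code == 0)
  )
  per_sub <- retrieved |>
    group_by(.data$subcategory) |>
    summarise(tp = sum(.data$code == 1), n = dplyr::n(), .groups = "drop")
  report <- validation_report(conf, subcategory_precision_table(per_sub))
  kappa <- NULL
  if (dplyr::n_distinct(coded$coder) >= 2) {
    coders <- unique(coded$coder)[1:2]
    wide <- coded |>
      filter(.data$coder %in% coders) |>
      tidyr::pivot_wider(id_cols = c("id", "subcategory"),
                         names_from = "coder", values_from = "code") |>
      tidyr::drop_na()
    if (nrow(wide) > 0) {
      kappa <- cohen_kappa_from_codes(wide[[coders[[1]]]], wide[[coders[[2]]]])
    }
  }
  paths <- c(report = file.path(dir, "validation_report.json"),
             manifest = file.path(dir, "validate_manifest.json"))
  jsonlite::write_json(
    list(confusion = unclass(report$confusion), metrics = report$metrics,
         rounded = report$rounded, kappa = kappa,
         precision_table = report$precision_table$table,
         average_precision_pct = report$precision_table$average_pct),
    paths[["report"]], auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(config, paths[["manifest"]],
                 inputs = list(coded = coded_path),
                 outputs = as.list(paths["report"]))
  invisible(paths)
}

#' @rdname pipeline_commands
#' @export
cmd_report <- function(stats_path, config, week = NULL) {
  if (!file.exists(stats_path)) {
    abort("weekly stats file is required", class = "infodemic_usage_error")
  }
  dir <- ensure_dir(config$out_dir)
  stats <- readr::read_csv(stats_path, col_types = readr::cols(),
                           progress = FALSE)
  week <- week %||% max(stats$week)
  flags <- detect_signals(stats, week, config$signals)
  lines <- render_weekly_report(flags, stats, week, config$signals)
  paths <- c(report = file.path(dir, sprintf("report_%s.md", week)),
             manifest = file.path(dir, "report_manifest.json"))
  writeLines(lines, paths[["report"]])
  write_manifest(config, paths[["manifest"]],
                 inputs = list(stats = stats_path, week = week),
                 outputs = as.list(paths["report"]))
  invisible(paths)
}
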