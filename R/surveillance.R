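# Weekly surveillance: per-topic volume / question / engagement aggregation,
# week-on-week velocity, information-void signal flagging, and trend
# summaries over a topic's weekly series.

#' Week-on-week velocity
#'
#' `velocity = (current - previous) / previous * 100` (a signed percentage,
#' never below -100). Undefined (NA) when the previous week had zero volume
#' or is unknown; undefined weeks are excluded from ranking and averages
#' rather than producing infinities.
#'
#' @param current,previous Numeric vectors of weekly mention volumes.
#' @return Numeric vector of percentages, NA where undefined.
#' @export
#' @examples
#' velocity(150, 100) # +50
#' velocity(0, 40)    # -100
velocity <- function(current, previous) {
  out <- (current - previous) / previous * 100
  out[is.na(previous) | previous <= 0] <- NA_real_
  out
}

#' Aggregate classification records into weekly per-topic statistics
#'
#' For every (subcategory, ISO week) cell: post volume, question volume and
#' share, summed engagement, previous-week volume and velocity. The week
#' calendar is made contiguous from the first to the last observed Monday
#' (gap weeks get zero rows), so velocities always compare adjacent calendar
#' weeks. Volume is conserved: summed over weeks it equals the number of
#' (post, topic) match pairs per topic.
#'
#' @param records Classification records from [classify_corpus()].
#' @param subcategories Optional character vector of topic ids to tabulate
#'   (e.g. the full taxonomy, so unmatched topics appear with zero volume);
#'   defaults to the topics observed in `records`.
#' @param weeks Optional Date vector of week-start Mondays for the calendar;
#'   defaults to the contiguous observed range.
#' @return A tibble: `subcategory`, `week`, `week_start`, `volume`,
#'   `question_volume`, `question_share`, `engagement_total`, `prev_volume`,
#'   `velocity`.
#' @export
weekly_aggregate <- function(records, subcategories = NULL, weeks = NULL) {
  pairs <- match_pairs(records)
  topics <- subcategories %||% sort(unique(pairs$subcategory))
  if (nrow(pairs) == 0 && is.null(weeks)) {
    return(tibble(subcategory = character(0), week = character(0),
                  week_start = as.Date(character(0)), volume = integer(0),
                  question_volume = integer(0), question_share = numeric(0),
                  engagement_total = integer(0), prev_volume = integer(0),
                  velocity = numeric(0)))
  }
  if (is.null(weeks)) {
    weeks <- seq(min(pairs$week_start), max(pairs$week_start), by = 7L)
  }
  agg <- pairs |>
    group_by(.data$subcategory, .data$week_start) |>
    summarise(volume = dplyr::n(),
              question_volume = sum(.data$is_question),
              engagement_total = sum(.data$engagement_total),
              .groups = "drop")
  full <- tidyr::expand_grid(subcategory = topics, week_start = weeks) |>
    left_join(agg, by = c("subcategory", "week_start")) |>
    mutate(
      volume = as.integer(dplyr::coalesce(.data$volume, 0L)),
      question_volume = as.integer(dplyr::coalesce(.data$question_volume, 0L)),
      engagement_total = as.integer(dplyr::coalesce(.data$engagement_total, 0L)),
      question_share = ifelse(.data$volume > 0,
                              .data$question_volume / .data$volume, NA_real_),
      week = iso_week_key(.data$week_start)
    ) |>
    arrange(.data$subcategory, .data$week_start) |>
    group_by(.data$subcategory) |>
    mutate(prev_volume = dplyr::lag(.data$volume),
           velocity = velocity(.data$volume, .data$prev_volume)) |>
    ungroup()
  full[, c("subcategory", "week", "week_start", "volume", "question_volume",
           "question_share", "engagement_total", "prev_volume", "velocity")]
}

#' Signal-detection configuration
#'
#' The study never quantifies "high velocity", "large proportion of
#' questions" or "high engagement" (those judgments were made by analysts);
#' these defaults make the flagging reproducible and are always recorded in
#' the report: velocity at or above +50%, question share strictly above the
#' cross-topic 80th percentile, engagement strictly above its 80th
#' percentile, at most 10 flags per week.
#'
#' @param velocity_threshold_pct Flag topics with velocity >= this percent.
#' @param question_share_quantile Cross-topic quantile a topic's question
#'   share must strictly exceed.
#' @param engagement_quantile Cross-topic quantile a topic's engagement must
#'   strictly exceed.
#' @param max_topics Maximum number of flags per week.
#' @return A `signal_config` list.
#' @export
signal_config <- function(velocity_threshold_pct = 50,
                          question_share_quantile = 0.8,
                          engagement_quantile = 0.8,
                          max_topics = 10) {
  stopifnot(max_topics >= 1,
            question_share_quantile > 0, question_share_quantile < 1,
            engagement_quantile > 0, engagement_quantile < 1)
  structure(list(velocity_threshold_pct = velocity_threshold_pct,
                 question_share_quantile = question_share_quantile,
                 engagement_quantile = engagement_quantile,
                 max_topics = max_topics),
            class = "signal_config")
}

#' Flag potential information voids for a week
#'
#' A topic is flagged when its velocity reaches the threshold, when its
#' question share or engagement strictly exceeds the cross-topic quantile, or
#' (for topics with no previous-week volume, whose velocity is undefined)
#' when its volume exceeds the median topic volume ("new topic"). Flags are
#' scored by the largest standardized exceedance among their triggers,
#' ranked, tie-broken by volume then id, and truncated to `max_topics`. The
#' result is invariant to the row order of `stats`.
#'
#' @param stats Weekly statistics from [weekly_aggregate()].
#' @param week Week to scan: an ISO week key (`"2020-W16"`) or a Date.
#' @param config A [signal_config()].
#' @return A tibble of flags: `subcategory`, `week`, `triggers` (list-column
#'   of trigger names), `score`, and the evidence columns `volume`,
#'   `question_volume`, `question_share`, `engagement_total`, `velocity`.
#' @export
detect_signals <- function(stats, week, config = signal_config()) {
  stopifnot(inherits(config, "signal_config"))
  key <- if (inherits(week, "Date")) iso_week_key(week) else as.character(week)
  wk <- stats[stats$week == key, ]
  if (nrow(wk) == 0) abort(sprintf("week %s not present in stats", key))
  wk <- arrange(wk, .data$subcategory)

  q_thr <- quantile(wk$question_share[wk$volume > 0],
                    config$question_share_quantile, na.rm = TRUE,
                    names = FALSE)
  e_thr <- quantile(wk$engagement_total, config$engagement_quantile,
                    names = FALSE)
  med_vol <- median(wk$volume)
  safe_sd <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) 1 else s
  }
  sd_v <- safe_sd(wk$velocity)
  sd_q <- safe_sd(wk$question_share)
  sd_e <- safe_sd(wk$engagement_total)
  sd_n <- safe_sd(wk$volume)

  rows <- lapply(seq_len(nrow(wk)), function(i) {
    r <- wk[i, ]
    triggers <- character(0)
    scores <- numeric(0)
    if (!is.na(r$velocity) && r$velocity >= config$velocity_threshold_pct) {
      triggers <- c(triggers, "high_velocity")
      scores <- c(scores, (r$velocity - config$velocity_threshold_pct) / sd_v)
    }
    if (is.na(r$velocity) && !is.na(r$prev_volume) && r$prev_volume == 0 &&
        r$volume > med_vol) {
      triggers <- c(triggers, "new_topic")
      scores <- c(scores, (r$volume - med_vol) / sd_n)
    }
    if (!is.na(q_thr) && !is.na(r$question_share) && r$volume > 0 &&
        r$question_share > q_thr) {
      triggers <- c(triggers, "high_question_share")
      scores <- c(scores, (r$question_share - q_thr) / sd_q)
    }
    if (r$engagement_total > e_thr) {
      triggers <- c(triggers, "high_engagement")
      scores <- c(scores, (r$engagement_total - e_thr) / sd_e)
    }
    if (length(triggers) == 0) return(NULL)
    tibble(subcategory = r$subcategory, week = key,
           triggers = list(triggers), score = max(scores),
           volume = r$volume, question_volume = r$question_volume,
           question_share = r$question_share,
           engagement_total = r$engagement_total, velocity = r$velocity)
  })
  flags <- dplyr::bind_rows(rows)
  if (nrow(flags) == 0) {
    return(tibble(subcategory = character(0), week = character(0),
                  triggers = list(), score = numeric(0), volume = integer(0),
                  question_volume = integer(0), question_share = numeric(0),
                  engagement_total = integer(0), velocity = numeric(0)))
  }
  flags <- flags[order(-flags$score, -flags$volume, flags$subcategory), ]
  head(flags, config$max_topics)
}

# ---- trend summaries over one topic's weekly volume series -------------

topic_velocities <- function(volumes) {
  n <- length(volumes)
  if (n < 2) return(numeric(0))
  velocity(volumes[-1], volumes[-n])
}

#' Trend summaries of a topic's weekly volume series
#'
#' `positive_velocity_weeks()` counts weeks with positive week-on-week
#' velocity; `avg_weekly_increase()` is the arithmetic mean of the defined
#' weekly velocities (undefined zero-previous weeks are excluded);
#' `longest_positive_streak()` is the longest run of consecutive
#' positive-velocity weeks. Series shorter than 2 weeks return NA.
#'
#' @param volumes Numeric vector of weekly volumes, in week order.
#' @return An integer count, a percentage, or an integer streak length.
#' @export
#' @examples
#' positive_velocity_weeks(c(100, 110, 105, 120)) # 2
#' avg_weekly_increase(c(100, 110, 105, 120))     # about +6.58
#' longest_positive_streak(c(1, 2, 4, 8))         # 3
positive_velocity_weeks <- function(volumes) {
  if (length(volumes) < 2) return(NA_integer_)
  sum(topic_velocities(volumes) > 0, na.rm = TRUE)
}

#' @rdname positive_velocity_weeks
#' @export
avg_weekly_increase <- function(volumes) {
  if (length(volumes) < 2) return(NA_real_)
  v <- topic_velocities(volumes)
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' @rdname positive_velocity_weeks
#' @export
longest_positive_streak <- function(volumes) {
  if (length(volumes) < 2) return(NA_integer_)
  pos <- topic_velocities(volumes) > 0
  pos[is.na(pos)] <- FALSE
  r <- rle(pos)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else as.integer(max(runs))
}

#' Per-topic trend table (positive weeks, mean velocity, longest streak)
#'
#' @param stats Weekly statistics from [weekly_aggregate()].
#' @return A tibble with one row per subcategory, sorted by
#'   `positive_weeks` descending.
#' @export
trend_summary <- function(stats) {
  stats |>
    arrange(.data$subcategory, .data$week_start) |>
    group_by(.data$subcategory) |>
    summarise(
      positive_weeks = positive_velocity_weeks(.data$volume),
      avg_weekly_increase_pct = avg_weekly_increase(.data$volume),
      longest_streak = longest_positive_streak(.data$volume),
      total_volume = sum(.data$volume),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$positive_weeks), .data$subcategory)
}

#' Most discussed topic per calendar month
#'
#' Weeks are assigned to the month of their Monday. Ties on the summed
#' volume are broken lexicographically and marked in the `tie` column.
#'
#' @param stats Weekly statistics from [weekly_aggregate()].
#' @return A tibble: `month` (`"YYYY-MM"`), `subcategory`, `volume`, `tie`.
#' @export
monthly_top_topics <- function(stats) {
  stats |>
    mutate(month = format(.data$week_start, "%Y-%m")) |>
    group_by(.data$month, .data$subcategory) |>
    summarise(volume = sum(.data$volume), .groups = "drop") |>
    group_by(.data$month) |>
    arrange(dplyr::desc(.data$volume), .data$subcategory, .by_group = TRUE) |>
    summarise(
      subcategory = dplyr::first(.data$subcategory),
      tie = sum(.data$volume == max(.data$volume)) > 1,
      volume = max(.data$volume),
      .groups = "drop"
    ) |>
    arrange(.data$month) |>
    select("month", "subcategory", "volume", "tie")
}

#' Share of the conversation retrieved by the taxonomy
#'
#' Taxonomy-matched volume as a fraction of the common-word baseline volume
#' (the study's analysis set was about 3% of the total conversation pool).
#' Multi-label matching can push the matched total above the baseline; that
#' is allowed with a warning.
#'
#' @param matched_total Number of (post, topic) matches or matched posts.
#' @param baseline_total Baseline (common-word) post volume; must be > 0.
#' @return Fraction `matched_total / baseline_total`.
#' @export
relevant_share <- function(matched_total, baseline_total) {
  if (is.na(baseline_total) || baseline_total <= 0) {
    abort("baseline_total must be positive")
  }
  if (matched_total > baseline_total) {
    warn("matched total exceeds baseline total (multi-label matching)")
  }
  matched_total / baseline_total
}
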