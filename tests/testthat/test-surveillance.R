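test_that("velocity follows the week-on-week percentage formula", {
  expect_equal(velocity(150, 100), 50)
  expect_equal(velocity(100, 100), 0)
  expect_equal(velocity(0, 40), -100)
  expect_true(is.na(velocity(10, 0)))
  expect_true(is.na(velocity(10, NA)))
  # vectorized, never below -100
  expect_true(all(velocity(0:10, rep(5, 11)) >= -100))
})

test_that("doubling then halving returns velocities +100 then -50", {
  v <- topic_series <- c(100, 200, 100)
  vels <- velocity(v[-1], v[-3])
  expect_equal(vels, c(100, -50))
})

test_that("weekly aggregation counts planted volumes and questions", {
  tax <- toy_taxonomy()
  texts <- c(rep("covid vaccine news", 6), rep("why covid vaccine now", 4))
  res <- classify_corpus(toy_posts(texts), tax)
  stats <- weekly_aggregate(res$records)
  row <- stats[stats$subcategory == "vaccines", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$volume, 10L)
  expect_equal(row$question_volume, 4L)
  expect_equal(row$question_share, 0.4)
  expect_true(is.na(row$velocity))  # first observed week
})

test_that("weekly aggregation is conservative and fills gap weeks", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 4, seed = 2)
  co <- generate_corpus(corpus_spec(fix, weeks = 5, base_volume = 12,
                                    background_volume = 5, seed = 23))
  res <- classify_corpus(co$posts, fix$taxonomy)
  stats <- weekly_aggregate(res$records,
                            subcategories = fix$taxonomy$subcategories$id)
  pairs <- match_pairs(res$records)
  # conservation: total volume equals the number of (post, topic) match pairs
  expect_equal(sum(stats$volume), nrow(pairs))
  per_topic <- tapply(stats$volume, stats$subcategory, sum)
  expect_equal(as.integer(per_topic[sort(unique(pairs$subcategory))]),
               as.integer(table(pairs$subcategory)))
  # calendar is contiguous Mondays for every topic
  for (sid in unique(stats$subcategory)) {
    wk <- sort(stats$week_start[stats$subcategory == sid])
    expect_equal(as.integer(diff(wk)), rep(7L, length(wk) - 1))
  }
  expect_equal(nrow(weekly_aggregate(res$records[0, ])), 0)
})

test_that("multi-label posts are counted once per matching topic", {
  tax <- toy_taxonomy()
  res <- classify_corpus(
    toy_posts(c("covid fever from airborne transmission",
                "covid cough update")), tax)
  stats <- weekly_aggregate(res$records)
  expect_equal(sum(stats$volume), 3L)      # 3 match pairs from 2 posts
  expect_gte(sum(stats$volume), nrow(res$records))
})

test_that("trend summaries match hand-computed values", {
  v <- c(100, 110, 105, 120)
  expect_equal(positive_velocity_weeks(v), 2L)
  expect_equal(avg_weekly_increase(v),
               mean(c(10, -100 * 5 / 110, 100 * 15 / 105)))
  expect_equal(round(avg_weekly_increase(v), 2), 6.58)
  expect_equal(longest_positive_streak(v), 1L)
  expect_equal(longest_positive_streak(c(1, 2, 4, 8)), 3L)
  expect_equal(positive_velocity_weeks(rep(7, 5)), 0L)
  expect_equal(avg_weekly_increase(rep(7, 5)), 0)
  expect_true(is.na(positive_velocity_weeks(10)))
  expect_true(is.na(avg_weekly_increase(10)))
  expect_true(is.na(longest_positive_streak(c())))
  # zero-previous weeks are excluded from the average, not treated as 0
  expect_equal(avg_weekly_increase(c(0, 10, 20)), 100)
})

test_that("monthly top topics follow volume with lexicographic tie-breaks", {
  stats <- tibble::tibble(
    subcategory = rep(c("a-topic", "b-topic"), each = 6),
    week_start = rep(seq(as.Date("2020-03-02"), by = 7, length.out = 6), 2),
    volume = c(10, 10, 10, 10, 10, 1, 2, 2, 2, 2, 2, 50)
  ) |>
    dplyr::mutate(week = iso_week_key(week_start))
  top <- monthly_top_topics(stats)
  expect_equal(top$subcategory[top$month == "2020-03"], "a-topic")
  expect_equal(top$subcategory[top$month == "2020-04"], "b-topic")
  expect_false(any(top$tie))
  # exact tie -> lexicographically first plus a tie marker
  stats2 <- stats |> dplyr::mutate(volume = 5)
  top2 <- monthly_top_topics(stats2)
  expect_equal(top2$subcategory, c("a-topic", "a-topic"))
  expect_true(all(top2$tie))
})

test_that("relevant_share contextualizes matched volume against baseline", {
  expect_equal(relevant_share(3, 100), 0.03)
  expect_equal(relevant_share(0, 100), 0)
  expect_error(relevant_share(5, 0), "positive")
  expect_warning(s <- relevant_share(120, 100), "multi-label")
  expect_equal(s, 1.2)
})

test_that("a planted surge is the top-ranked signal", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 6, seed = 6)
  sp <- corpus_spec(fix, weeks = 4, base_volume = 25, background_volume = 20,
                    seed = 41,
                    trajectory = list(topic03 = list(kind = "surge",
                                                     week = 3, mult = 8)))
  co <- generate_corpus(sp)
  res <- classify_corpus(co$posts, fix$taxonomy)
  stats <- weekly_aggregate(res$records,
                            subcategories = fix$taxonomy$subcategories$id)
  flags <- detect_signals(stats, "2020-W15")
  expect_gt(nrow(flags), 0)
  expect_equal(flags$subcategory[[1]], "topic03")
  expect_true("high_velocity" %in% flags$triggers[[1]])
})

test_that("flat identical topics raise no flags at default thresholds", {
  weeks <- seq(as.Date("2020-03-23"), by = 7, length.out = 3)
  stats <- tidyr::expand_grid(subcategory = sprintf("t%02d", 1:5),
                              week_start = weeks) |>
    dplyr::mutate(week = iso_week_key(week_start), volume = 50L,
                  question_volume = 10L, question_share = 0.2,
                  engagement_total = 100L) |>
    dplyr::group_by(subcategory) |>
    dplyr::mutate(prev_volume = dplyr::lag(volume),
                  velocity = velocity(volume, prev_volume)) |>
    dplyr::ungroup()
  flags <- detect_signals(stats, "2020-W14")
  expect_equal(nrow(flags), 0)
})

test_that("flags are capped at max_topics and ordered by score", {
  weeks <- seq(as.Date("2020-03-23"), by = 7, length.out = 2)
  n <- 12
  stats <- tidyr::expand_grid(subcategory = sprintf("t%02d", 1:n),
                              week_start = weeks) |>
    dplyr::arrange(subcategory, week_start) |>
    dplyr::group_by(subcategory) |>
    dplyr::mutate(
      volume = ifelse(dplyr::row_number() == 1, 100L,
                      100L + 100L * match(subcategory[[1]],
                                          sprintf("t%02d", 1:n))),
      week = iso_week_key(week_start),
      question_volume = 0L, question_share = 0,
      engagement_total = 10L,
      prev_volume = dplyr::lag(volume),
      velocity = velocity(volume, prev_volume)
    ) |>
    dplyr::ungroup()
  flags <- detect_signals(stats, "2020-W14")
  expect_equal(nrow(flags), 10)
  expect_equal(flags$score, sort(flags$score, decreasing = TRUE))
  # the 12 topics all surge; the two weakest surges are dropped
  expect_false(any(c("t01", "t02") %in% flags$subcategory))
})

test_that("detect_signals is invariant to row order and validates the week", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 5, seed = 9)
  co <- generate_corpus(corpus_spec(fix, weeks = 3, base_volume = 20,
                                    background_volume = 0, seed = 31))
  res <- classify_corpus(co$posts, fix$taxonomy)
  stats <- weekly_aggregate(res$records)
  f1 <- detect_signals(stats, "2020-W14")
  perm <- withr::with_seed(8, sample.int(nrow(stats)))
  f2 <- detect_signals(stats[perm, ], "2020-W14")
  expect_equal(f1, f2)
  expect_error(detect_signals(stats, "2031-W01"), "not present")
})
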