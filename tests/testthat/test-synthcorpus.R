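test_that("taxonomy fixtures have the declared structure and shared keywords", {
  fix <- make_taxonomy_fixture()
  expect_length(fix$taxonomy$categories, 5)
  expect_equal(nrow(fix$taxonomy$subcategories), 35)
  expect_setequal(fix$taxonomy$languages, c("en", "fr"))

  fix2 <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 6,
                                seed = 8, n_shared = 2)
  # each shared ambiguous keyword appears in exactly its two declared queries
  for (sh in fix2$shared) {
    hits <- vapply(fix2$taxonomy$subcategories$id, function(sid) {
      grepl(sh$word, deparse_query(fix2$taxonomy$queries[[sid]]$en),
            fixed = TRUE)
    }, logical(1))
    expect_setequal(names(hits)[hits], sh$topics)
    # and a post using it (plus covid) matches both subcategories
    rec <- classify_corpus(
      posts_tibble("amb1", paste("covid", sh$word), "en",
                   "2020-03-23T00:00:00Z", "twitter"),
      fix2$taxonomy, warn_unsupported = FALSE)$records
    expect_setequal(rec$matched[[1]], sh$topics)
  }
  # seed stability
  expect_identical(make_taxonomy_fixture(seed = 8),
                   make_taxonomy_fixture(seed = 8))
  expect_error(make_taxonomy_fixture(n_categories = 5, n_subcategories = 3),
               "at least")
})

test_that("generation is deterministic given the spec seed", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 2, seed = 1)
  sp <- corpus_spec(fix, weeks = 4, base_volume = 10, background_volume = 5,
                    seed = 7)
  c1 <- generate_corpus(sp)
  c2 <- generate_corpus(sp)
  expect_identical(c1$posts, c2$posts)
  expect_identical(c1$truth, c2$truth)
  # byte-identical on disk too
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(c1$posts, p1)
  write_posts(c2$posts, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the corpus
  c3 <- generate_corpus(corpus_spec(fix, weeks = 4, base_volume = 10,
                                    background_volume = 5, seed = 8))
  expect_false(identical(c1$posts, c3$posts))
})

test_that("surge trajectories scale the planted week's Poisson volume", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 3, seed = 2)
  base <- 30
  mult <- 8
  sp <- corpus_spec(fix, weeks = 4, base_volume = base, background_volume = 0,
                    fp_rate = 0, fn_rate = 0, seed = 13,
                    trajectory = list(topic01 = list(kind = "surge",
                                                     week = 3, mult = mult)))
  co <- generate_corpus(sp)
  wk3 <- sum(co$truth$topic == "topic01" &
               co$truth$week == "2020-W15", na.rm = TRUE)
  lambda <- base * mult
  expect_gt(wk3, qpois(0.005, lambda))
  expect_lt(wk3, qpois(0.995, lambda))
  # non-surge weeks stay near base volume
  wk1 <- sum(co$truth$topic == "topic01" &
               co$truth$week == "2020-W13", na.rm = TRUE)
  expect_lt(wk1, qpois(0.995, base))
})

test_that("planted question and contamination rates are recovered", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 4, seed = 5)
  sp <- corpus_spec(fix, weeks = 4, base_volume = 60, background_volume = 0,
                    question_rate = 0.4, fp_rate = 0.1, fn_rate = 0.15,
                    seed = 17)
  co <- generate_corpus(sp)
  rel <- co$truth[co$truth$type == "tp", ]
  q <- mean(rel$is_question)
  half <- 2.58 * sqrt(0.4 * 0.6 / nrow(rel))
  expect_gt(q, 0.4 - half)
  expect_lt(q, 0.4 + half)
  # the question templates actually trigger the question detector
  res <- classify_corpus(co$posts, fix$taxonomy)
  joined <- dplyr::left_join(co$truth, res$records,
                             by = c(id = "post_id"))
  expect_true(all(joined$is_question.y[joined$is_question.x]))
  # planted FP share among retrieved
  retr <- co$truth$type %in% c("tp", "fp")
  fp_share <- mean(co$truth$type[retr] == "fp")
  half_fp <- 2.58 * sqrt(0.1 * 0.9 / sum(retr))
  expect_gt(fp_share, 0.1 - half_fp)
  expect_lt(fp_share, 0.1 + half_fp)
})

test_that("false negatives mention covid but match no taxonomy search", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 3, seed = 5)
  co <- generate_corpus(corpus_spec(fix, weeks = 2, base_volume = 30,
                                    background_volume = 10, fn_rate = 0.2,
                                    seed = 29))
  res <- classify_corpus(co$posts, fix$taxonomy)
  joined <- dplyr::left_join(co$truth, res$records, by = c(id = "post_id"))
  fn <- joined[joined$type == "fn", ]
  expect_gt(nrow(fn), 0)
  expect_true(all(fn$n_matched == 0))
  expect_true(all(grepl("covid", co$posts$text[co$posts$id %in% fn$id])))
  # background posts match nothing and skip the covid anchor
  bg <- joined[joined$type == "background", ]
  expect_true(all(bg$n_matched == 0))
  expect_false(any(grepl("covid", co$posts$text[co$posts$id %in% bg$id])))
})

test_that("simulated coders reach kappa 1 at zero error and near 0 at random", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 3, seed = 5)
  co <- generate_corpus(corpus_spec(fix, weeks = 2, base_volume = 40,
                                    fp_rate = 0.3, seed = 37))
  coded0 <- simulate_coding(co$truth, error_rate = 0, seed = 1)
  wide0 <- tidyr::pivot_wider(coded0, id_cols = "id", names_from = "coder",
                              values_from = "code")
  expect_equal(cohen_kappa_from_codes(wide0$A, wide0$B)$kappa, 1)
  expect_identical(simulate_coding(co$truth, 0.1, seed = 3),
                   simulate_coding(co$truth, 0.1, seed = 3))
  coded49 <- simulate_coding(co$truth, error_rate = 0.49, seed = 2)
  wide49 <- tidyr::pivot_wider(coded49, id_cols = "id", names_from = "coder",
                               values_from = "code")
  k <- cohen_kappa_from_codes(wide49$A, wide49$B)$kappa
  expect_lt(abs(k), 2.58 / sqrt(nrow(wide49)) + 0.05)
  expect_error(simulate_coding(co$truth, 0.6, seed = 1))
})

test_that("invalid specs are rejected", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 3, seed = 1)
  expect_error(corpus_spec(fix, fp_rate = 1.5))
  expect_error(corpus_spec(fix, fn_rate = 0.5))
  expect_error(corpus_spec(fix, start = as.Date("2020-03-24")), "Monday")
  expect_error(corpus_spec(fix, trajectory = list(bogus = list(kind = "flat"))),
               "unknown topic")
  expect_error(corpus_spec(fix, platform_mix = c(twitter = 0.5)))
})
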