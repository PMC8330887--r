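precision_fixture <- function() {
  readr::read_csv(
    system.file("extdata", "retrieval_precision_counts.csv",
                package = "infodemic"),
    col_types = readr::cols(subcategory = readr::col_character(),
                            category = readr::col_character(),
                            tp = readr::col_integer(),
                            tp_retest = readr::col_integer(),
                            n = readr::col_integer())
  )
}

test_that("precision and recall rates apply the published formulas", {
  expect_equal(round(precision_rate(217, 83), 1), 72.3)
  expect_equal(precision_rate(300, 0), 100)
  expect_equal(precision_rate(0, 300), 0)
  expect_error(precision_rate(0, 0), "undefined")
  expect_equal(round(recall_rate(875, 304)), 74)
  expect_equal(recall_rate(10, 0), 100)
  expect_equal(recall_rate(0, 10), 0)
  expect_error(recall_rate(0, 0), "undefined")
})

test_that("F-scores match the published formulas and orderings", {
  f <- f_scores(0.875, 0.742)
  expect_equal(round(f$f1, 2), 0.80)
  expect_equal(round(f$f_half, 2), 0.84)
  expect_equal(f_scores(0.6, 0.6), list(f1 = 0.6, f_half = 0.6))
  expect_equal(f_scores(1, 1), list(f1 = 1, f_half = 1))
  expect_error(f_scores(0, 0), "undefined")
  # F0.5 > F1 iff precision > recall, equality iff equal
  set.seed(77)
  for (i in 1:100) {
    p <- runif(1, 0.05, 1)
    r <- runif(1, 0.05, 1)
    f <- f_scores(p, r)
    if (p > r) expect_gt(f$f_half, f$f1)
    if (p < r) expect_lt(f$f_half, f$f1)
    if (p == r) expect_equal(f$f_half, f$f1)
  }
})

test_that("Cohen kappa from agreement and from codes agree with a 2x2 oracle", {
  expect_equal(cohen_kappa_from_agreement(0.93, 0.50), 0.86)
  expect_equal(cohen_kappa_from_agreement(0.4, 0.4), 0)
  expect_error(cohen_kappa_from_agreement(0.9, 1), "undefined")

  # 20 pairs, 18 agreements, balanced marginals
  c1 <- c(rep(1, 10), rep(0, 10))
  c2 <- c(rep(1, 9), 0, 1, rep(0, 9))
  k <- cohen_kappa_from_codes(c1, c2)
  # independent recomputation from the contingency table
  tab <- table(factor(c1, c(0, 1)), factor(c2, c(0, 1)))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  expect_equal(k$p_o, p_o)
  expect_equal(k$p_e, p_e)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))

  # swapping the coders leaves kappa unchanged
  k2 <- cohen_kappa_from_codes(c2, c1)
  expect_equal(k2$kappa, k$kappa)
})

test_that("per-subcategory table reproduces the published averages", {
  counts <- precision_fixture()
  initial <- subcategory_precision_table(counts[, c("subcategory", "tp", "n")])
  expect_equal(initial$average_pct, 82)
  expect_length(initial$below_target, 7)
  expect_equal(min(initial$table$precision_pct), 42)
  expect_equal(max(initial$table$precision_pct), 100)
  # 71.7 is not below the strict 70% target
  expect_false("The Illness - Demographics - Sex" %in% initial$below_target)

  retested <- subcategory_precision_table(counts)
  expect_equal(retested$average_final_pct, 87)
  expect_equal(retested$range_final_pct, c(72, 100))
  expect_equal(min(retested$table$final_pct), 71.7)

  perfect <- subcategory_precision_table(
    tibble::tibble(subcategory = c("a", "b"), tp = c(300, 300), n = 300))
  expect_equal(perfect$average_pct, 100)
  expect_length(perfect$below_target, 0)

  expect_error(subcategory_precision_table(
    tibble::tibble(subcategory = "a", tp = NA_integer_, n = 300)), "missing")
})

test_that("downweighting scales proportionally with exact integer totals", {
  expect_equal(downweight_counts(c(8750, 1250), 1000), c(875L, 125L))
  expect_equal(downweight_counts(c(875, 125), 1000), c(875L, 125L))
  expect_equal(downweight_counts(c(1, 1, 1), 100), c(34L, 33L, 33L))
  expect_error(downweight_counts(c(0, 0), 100), "zero")
  set.seed(14)
  for (i in 1:25) {
    counts <- rpois(sample(2:6, 1), 50) + 1
    target <- sample(50:500, 1)
    scaled <- downweight_counts(counts, target)
    expect_equal(sum(scaled), target)
    expect_true(all(abs(scaled - counts / sum(counts) * target) < 1))
  }
})

test_that("coding samples are seeded, capped and warn when short", {
  pairs <- tibble::tibble(
    post_id = sprintf("p%03d", 1:120),
    subcategory = rep(c("a", "b", "c"), each = 40)
  )
  s1 <- build_coding_sample(pairs, 10, seed = 99)
  s2 <- build_coding_sample(pairs, 10, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 30)
  expect_equal(unname(table(s1$subcategory)["a"]), 10)
  expect_false(any(duplicated(s1$post_id)))
  s3 <- build_coding_sample(pairs, 10, seed = 5)
  expect_false(identical(s1$post_id, s3$post_id))
  expect_warning(short <- build_coding_sample(pairs[1:5, ], 10, seed = 1),
                 "only 5 records")
  expect_equal(nrow(short), 5)
  spot <- spot_check_sample(s1, fraction = 0.1, seed = 1)
  expect_equal(nrow(spot), 3)
})

test_that("validation_report assembles all metrics from a confusion table", {
  conf <- confusion_counts(tp = 875, fp = 125, fn = 304, tn = 696)
  rep <- validation_report(conf)
  expect_equal(rep$rounded$recall_pct, 74)
  expect_equal(rep$rounded$f1, 0.80)
  expect_equal(rep$rounded$f_half, 0.84)
  expect_equal(rep$rounded$not_retrieved_irrelevant_pct, 70)
  expect_equal(rep$rounded$precision_pct, 88)
  # arbitrary counts: metrics equal an independent recomputation
  set.seed(21)
  for (i in 1:20) {
    cc <- rpois(4, 80) + 1
    conf <- confusion_counts(cc[1], cc[2], cc[3], cc[4])
    m <- validation_report(conf)$metrics
    expect_equal(m$precision_pct, 100 * cc[1] / (cc[1] + cc[2]))
    expect_equal(m$recall_pct, 100 * cc[1] / (cc[1] + cc[3]))
    p <- cc[1] / (cc[1] + cc[2]); r <- cc[1] / (cc[1] + cc[3])
    expect_equal(m$f1, 2 * p * r / (p + r))
    expect_equal(m$f_half, 1.25 * p * r / (0.25 * p + r))
  }
  expect_error(confusion_counts(-1, 0, 0, 0))
})

test_that("precision/recall via the sample-code-confusion path equal direct counting", {
  fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 4, seed = 3)
  co <- generate_corpus(corpus_spec(fix, weeks = 3, base_volume = 25,
                                    background_volume = 10, fp_rate = 0.2,
                                    fn_rate = 0.1, seed = 55))
  res <- classify_corpus(co$posts, fix$taxonomy)
  truth <- co$truth

  # retrieved leg: every (post, matched topic) pair coded by ground truth
  pairs <- match_pairs(res$records) |>
    dplyr::left_join(truth[, c("id", "topic", "is_relevant")],
                     by = c(post_id = "id"))
  retrieved_code <- as.integer(pairs$is_relevant & pairs$topic == pairs$subcategory)
  # not-retrieved leg: posts mentioning covid with no match
  unmatched <- res$records$post_id[res$records$n_matched == 0]
  nr <- truth[truth$id %in% unmatched & truth$type != "background", ]
  conf <- confusion_counts(tp = sum(retrieved_code == 1),
                           fp = sum(retrieved_code == 0),
                           fn = sum(nr$is_relevant),
                           tn = sum(!nr$is_relevant))
  m <- validation_report(conf)$metrics

  direct <- evaluate_against_truth(res$records, truth)
  expect_equal(m$precision_pct, direct$precision_pct)
  expect_equal(m$recall_pct, direct$recall_pct)
})
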