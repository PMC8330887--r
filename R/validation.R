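# Retrieval-validation protocol: per-subcategory precision from coded
# retrieved samples, corpus recall from a coded "not retrieved" sample,
# F1/F0.5, Cohen's kappa for intercoder reliability, coding-sample
# construction, and confusion-table downweighting.
#
# Rounding convention (matching the published tables): per-subcategory
# precision to 1 decimal place, corpus-level averages to whole percent,
# F-scores and kappa to 2 decimals. Averages are unweighted means over the
# 1-dp subcategory rates, which is the convention that reproduces the
# published corpus averages; the "below target" comparison is strict (<).

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative counts. `tp + fp` is the coded retrieved
#'   sample, `fn + tn` the coded not-retrieved sample.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_counts")
}

#' Retrieval precision and recall rates
#'
#' `precision_rate()` is `TP / (TP + FP) * 100`: the share of retrieved posts
#' the coders judged relevant to their subcategory. `recall_rate()` is
#' `TP / (TP + FN) * 100`: the share of all relevant posts the taxonomy
#' retrieved, with FN estimated from coding a "not retrieved" sample.
#'
#' @param tp,fp,fn Non-negative counts; the denominator must be positive.
#' @return Percentage (unrounded; tables apply the reporting convention).
#' @export
#' @examples
#' round(precision_rate(217, 83), 1) # 72.3
#' round(recall_rate(875, 304))      # 74
precision_rate <- function(tp, fp) {
  if (tp + fp <= 0) abort("precision undefined: no retrieved posts coded")
  tp / (tp + fp) * 100
}

#' @rdname precision_rate
#' @export
recall_rate <- function(tp, fn) {
  if (tp + fn <= 0) abort("recall undefined: no relevant posts coded")
  tp / (tp + fn) * 100
}

#' F1 and F0.5 scores
#'
#' `F1 = 2 p r / (p + r)` and `F0.5 = 1.25 p r / (0.25 p + r)`, on fractions
#' in \[0, 1\]. F0.5 weights precision over recall: in retrieval validation
#' for signal detection it matters more that retrieved posts are correctly
#' classified than that every relevant post is collected, so F0.5 > F1
#' whenever precision > recall.
#'
#' @param precision,recall Fractions in \[0, 1\], not both zero.
#' @return A list with `f1` and `f_half` (unrounded).
#' @export
#' @examples
#' f_scores(0.875, 0.742) # f1 ~ 0.80, f_half ~ 0.84
f_scores <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall <= 0) abort("F-scores undefined: precision + recall = 0")
  list(
    f1 = 2 * precision * recall / (precision + recall),
    f_half = 1.25 * precision * recall / (0.25 * precision + recall)
  )
}

#' Cohen's kappa for binary intercoder reliability
#'
#' `cohen_kappa_from_agreement()` applies `kappa = (p_o - p_e) / (1 - p_e)`
#' to observed and expected agreement. `cohen_kappa_from_codes()` computes
#' both from paired binary codes: `p_o` is the fraction of agreeing pairs,
#' `p_e` the chance agreement from the two coders' marginals.
#'
#' @param p_o Observed agreement in \[0, 1\].
#' @param p_e Expected (chance) agreement in \[0, 1); `p_e = 1` is an error.
#' @return `cohen_kappa_from_agreement()`: the kappa value.
#' @export
#' @examples
#' cohen_kappa_from_agreement(0.93, 0.50) # 0.86
cohen_kappa_from_agreement <- function(p_o, p_e) {
  stopifnot(p_o >= 0, p_o <= 1, p_e >= 0)
  if (p_e >= 1) abort("kappa undefined: expected agreement is 1")
  (p_o - p_e) / (1 - p_e)
}

#' @rdname cohen_kappa_from_agreement
#' @param codes1,codes2 Equal-length vectors of 0/1 codes from two coders.
#' @return `cohen_kappa_from_codes()`: a list with `kappa`, `p_o`, `p_e`.
#' @export
cohen_kappa_from_codes <- function(codes1, codes2) {
  stopifnot(length(codes1) == length(codes2), length(codes1) > 0,
            all(codes1 %in% c(0, 1)), all(codes2 %in% c(0, 1)))
  p_o <- mean(codes1 == codes2)
  p_e <- sum(vapply(c(0, 1), function(v) mean(codes1 == v) * mean(codes2 == v),
                    numeric(1)))
  list(kappa = cohen_kappa_from_agreement(p_o, p_e), p_o = p_o, p_e = p_e)
}

#' Per-subcategory precision table with corpus average and below-target list
#'
#' Takes per-subcategory coded true-positive counts (the study coded 300
#' posts per subcategory search), reports each subcategory's precision to
#' 1 decimal place, the unweighted corpus average rounded to whole percent,
#' and the subcategories strictly below the target minimum. When retest
#' counts are present (searches whose keywords were revised and re-coded),
#' the same summaries are reported for the final rates.
#'
#' @param counts Data frame with columns `subcategory`, `tp` and either `n`
#'   (coded sample size per subcategory) or `fp`; optional `tp_retest` (NA
#'   where a search was not retested).
#' @param n_coded Default coded sample size when `counts` has no `n` column.
#' @param target_min_pct Target minimum precision (strictly-below flags).
#' @return A list: `table` (per-subcategory `precision_pct`, `retest_pct`,
#'   `final_pct`, `below_target`), `average_pct`, `below_target` ids,
#'   `average_final_pct`, `range_final_pct` (rounded to whole percent).
#' @export
subcategory_precision_table <- function(counts, n_coded = 300,
                                        target_min_pct = 70) {
  counts <- as_tibble(counts)
  stopifnot(all(c("subcategory", "tp") %in% names(counts)))
  if (anyNA(counts$tp)) abort("missing tp count for some subcategory")
  n <- if ("n" %in% names(counts)) counts$n else
    if ("fp" %in% names(counts)) counts$tp + counts$fp else n_coded
  pct <- round_half_up(mapply(function(tp, nn) precision_rate(tp, nn - tp),
                              counts$tp, n), 1)
  retest_pct <- if ("tp_retest" %in% names(counts)) {
    ifelse(is.na(counts$tp_retest), NA_real_,
           round_half_up(counts$tp_retest / n * 100, 1))
  } else {
    rep(NA_real_, nrow(counts))
  }
  final_pct <- dplyr::coalesce(retest_pct, pct)
  table <- tibble(
    subcategory = counts$subcategory,
    n_coded = n,
    precision_pct = pct,
    retest_pct = retest_pct,
    final_pct = final_pct,
    below_target = pct < target_min_pct
  )
  list(
    table = table,
    average_pct = round_half_up(mean(pct)),
    below_target = table$subcategory[table$below_target],
    average_final_pct = round_half_up(mean(final_pct)),
    range_final_pct = round_half_up(range(final_pct))
  )
}

#' Downweight counts to a target total
#'
#' Proportional scaling with largest-remainder rounding, so the scaled
#' counts are integers summing exactly to `target_total` (used to downweight
#' the coded "retrieved" sample to the size of the "not retrieved" sample
#' before combining them in one confusion table).
#'
#' @param counts Non-negative numeric vector with positive sum.
#' @param target_total Positive integer target sum.
#' @return Integer vector of the same length summing to `target_total`.
#' @export
#' @examples
#' downweight_counts(c(8750, 1250), 1000) # 875 125
#' downweight_counts(c(1, 1, 1), 100)     # 34 33 33
downweight_counts <- function(counts, target_total) {
  stopifnot(all(counts >= 0), target_total > 0)
  total <- sum(counts)
  if (total <= 0) abort("cannot downweight: counts sum to zero")
  exact <- counts / total * target_total
  base <- floor(exact)
  short <- round(target_total - sum(base))
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Draw a seeded coding sample from retrieval results
#'
#' Uniform sampling without replacement of up to `per_subcategory_n` match
#' pairs per subcategory (the study coded 300 per search, 10,500 in total
#' over 35 searches). Subcategories with fewer records contribute all of
#' them, with a warning. The same seed always yields the same sample.
#'
#' @param pairs Match pairs ([match_pairs()]) or any data frame with
#'   `post_id` and `subcategory` columns.
#' @param per_subcategory_n Sample size per subcategory.
#' @param seed Integer seed.
#' @return A tibble of sampled rows.
#' @export
build_coding_sample <- function(pairs, per_subcategory_n, seed) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("post_id", "subcategory") %in% names(pairs)),
            per_subcategory_n >= 1)
  withr::with_seed(seed, {
    out <- pairs |>
      group_by(.data$subcategory) |>
      group_modify(function(g, key) {
        if (nrow(g) < per_subcategory_n) {
          warn(sprintf("subcategory '%s': only %d records for a sample of %d",
                       key$subcategory, nrow(g), per_subcategory_n))
          return(g)
        }
        g[sample.int(nrow(g), per_subcategory_n), ]
      }) |>
      ungroup()
  })
  out
}

#' @rdname build_coding_sample
#' @param sample A coding sample from `build_coding_sample()`.
#' @param fraction Spot-check fraction per subcategory (default 10%, the
#'   share re-coded by a second reviewer).
#' @export
spot_check_sample <- function(sample, fraction = 0.1, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  withr::with_seed(seed, {
    out <- sample |>
      group_by(.data$subcategory) |>
      group_modify(function(g, key) {
        k <- max(1L, floor(nrow(g) * fraction))
        g[sample.int(nrow(g), k), ]
      }) |>
      ungroup()
  })
  out
}

#' Assemble the full validation report
#'
#' Computes every retrieval metric from a confusion table: precision and
#' recall, F1 and F0.5, and the share of the not-retrieved sample coded
#' irrelevant (the true-negative rate of the not-retrieved sample). Metrics
#' are reported both raw and under the publication rounding convention.
#'
#' @param confusion A [confusion_counts()] object.
#' @param precision_table Optional result of
#'   [subcategory_precision_table()], included verbatim.
#' @return A `validation_report` list with elements `confusion`, `metrics`
#'   (raw), `rounded`, and optionally `precision_table`.
#' @export
validation_report <- function(confusion, precision_table = NULL) {
  stopifnot(inherits(confusion, "confusion_counts"))
  p <- precision_rate(confusion$tp, confusion$fp)
  r <- recall_rate(confusion$tp, confusion$fn)
  f <- f_scores(p / 100, r / 100)
  tn_share <- confusion$tn / (confusion$tn + confusion$fn) * 100
  metrics <- list(precision_pct = p, recall_pct = r, f1 = f$f1,
                  f_half = f$f_half, not_retrieved_irrelevant_pct = tn_share)
  rounded <- list(
    precision_pct = round_half_up(p),
    recall_pct = round_half_up(r),
    f1 = round_half_up(f$f1, 2),
    f_half = round_half_up(f$f_half, 2),
    not_retrieved_irrelevant_pct = round_half_up(tn_share)
  )
  structure(list(confusion = confusion, metrics = metrics, rounded = rounded,
                 precision_table = precision_table),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  r <- x$rounded
  cat(sprintf(paste0("<validation_report> precision %s%%, recall %s%%, ",
                     "F1 %.2f, F0.5 %.2f, not-retrieved irrelevant %s%%\n"),
              r$precision_pct, r$recall_pct, r$f1, r$f_half,
              r$not_retrieved_irrelevant_pct))
  invisible(x)
}
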