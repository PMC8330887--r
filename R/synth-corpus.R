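# Seeded synthetic corpora with ground truth. The generator emulates the
# statistical shape of a pandemic social-listening feed — per-topic weekly
# Poisson volumes with injectable surges, a per-topic question rate, planted
# false positives (topic keywords out of context) and false negatives
# (relevant posts phrased without taxonomy keywords), a Twitter-dominant
# platform mix, and heavy-tailed (discrete log-normal) engagement — without
# attempting linguistic realism: templates only need to exercise the
# token-level matcher.

# Published platform shares (Twitter 87.02%, blogs 5.34%, Reddit 4.34%,
# message boards 2.14%, news comments 0.89%, reviews 0.13%, Instagram 0.12%,
# Facebook 0.03%; YouTube listed as a source with no printed share),
# normalized to sum to 1.
default_platform_mix <- function() {
  mix <- c(twitter = 0.8702, blog = 0.0534, reddit = 0.0434,
           message_board = 0.0214, news_comment = 0.0089, review = 0.0013,
           instagram = 0.0012, facebook = 0.0003, youtube = 0)
  mix / sum(mix)
}

#' Generate a synthetic taxonomy fixture with a keyword bank
#'
#' Builds a taxonomy whose subcategory searches use disjoint-by-construction
#' keyword stems (`t01alpha`, `t01beta`, a two-token phrase, French variants
#' with an `fr` suffix), every query anchored on the token `covid`. A few
#' deliberately ambiguous keywords are shared across pairs of subcategories
#' to exercise multi-label matching, and each subcategory gets a synonym
#' that appears in no query (used to plant false negatives).
#'
#' @param n_categories,n_subcategories Structure of the fixture (the
#'   reference taxonomy has 5 categories and 35 subcategories).
#' @param languages Language tags (default English and French).
#' @param seed Integer seed (controls which subcategory pairs share an
#'   ambiguous keyword).
#' @param n_shared Number of shared ambiguous keywords.
#' @return A `taxonomy_fixture` list: `taxonomy`, `keywords` (per
#'   subcategory and language), `phrases`, `synonyms`, `shared`.
#' @export
#' @examples
#' fix <- make_taxonomy_fixture(n_categories = 2, n_subcategories = 4)
#' fix$taxonomy
make_taxonomy_fixture <- function(n_categories = 5, n_subcategories = 35,
                                  languages = c("en", "fr"), seed = 1,
                                  n_shared = 2) {
  if (n_subcategories < n_categories) {
    abort("n_subcategories must be at least n_categories")
  }
  ids <- sprintf("topic%02d", seq_len(n_subcategories))
  cats <- sprintf("category-%d", seq_len(n_categories))
  cat_of <- cats[((seq_len(n_subcategories) - 1) %% n_categories) + 1]

  suffix <- function(lang) if (lang == "en") "" else lang
  stem <- sprintf("t%02d", seq_len(n_subcategories))

  keywords <- lapply(seq_len(n_subcategories), function(i) {
    lapply(setNames(languages, languages), function(lang) {
      paste0(stem[[i]], c("alpha", "beta"), suffix(lang))
    })
  })
  phrases <- lapply(seq_len(n_subcategories), function(i) {
    lapply(setNames(languages, languages), function(lang) {
      c(paste0(stem[[i]], "ph", suffix(lang)), "bulletin")
    })
  })
  synonyms <- lapply(seq_len(n_subcategories), function(i) {
    lapply(setNames(languages, languages), function(lang) {
      paste0(stem[[i]], "syn", suffix(lang))
    })
  })
  names(keywords) <- names(phrases) <- names(synonyms) <- ids

  # ambiguous keywords shared by pairs of subcategories
  n_shared <- min(n_shared, floor(n_subcategories / 2))
  shared <- list()
  if (n_shared > 0) {
    pick <- withr::with_seed(seed, {
      matrix(sample(seq_len(n_subcategories), 2 * n_shared), ncol = 2)
    })
    for (k in seq_len(n_shared)) {
      shared[[k]] <- list(word = sprintf("shared%02d", k),
                          topics = ids[pick[k, ]])
    }
  }

  query_for <- function(i, lang) {
    alts <- c(keywords[[i]][[lang]],
              sprintf('"%s"', paste(phrases[[i]][[lang]], collapse = " ")))
    for (sh in shared) {
      if (ids[[i]] %in% sh$topics) {
        alts <- c(alts, paste0(sh$word, suffix(lang)))
      }
    }
    sprintf("covid AND (%s)", paste(alts, collapse = " OR "))
  }

  subs <- tibble(id = ids, category = cat_of, name = ids)
  for (lang in languages) {
    subs[[paste0("query_", lang)]] <-
      vapply(seq_len(n_subcategories), query_for, character(1), lang = lang)
  }

  structure(
    list(
      taxonomy = taxonomy(categories = cats, subcategories = subs,
                          languages = languages,
                          expected_categories = n_categories,
                          expected_subcategories = n_subcategories),
      keywords = keywords, phrases = phrases, synonyms = synonyms,
      shared = shared
    ),
    class = "taxonomy_fixture"
  )
}

#' Specify a synthetic corpus
#'
#' The specification fixes the study conditions the generator emulates:
#' weekly Poisson volumes per topic around a base level and trajectory
#' (`flat`, `trend`, or `surge`), a per-topic question rate, planted
#' false-positive and false-negative rates, the Twitter-dominant platform
#' mix, discrete log-normal engagement, the language mix, and a weekly
#' volume of background posts that mention no taxonomy keyword.
#'
#' False positives are drawn binomially among a topic's retrieved posts, so
#' expected retrieval precision is `1 - fp_rate`; each true positive spawns
#' an unretrievable relevant companion with odds `fn_rate / (1 - fn_rate)`,
#' so expected recall is `1 - fn_rate`.
#'
#' @param fixture A [make_taxonomy_fixture()] result.
#' @param weeks Number of ISO weeks to simulate.
#' @param start First Monday (the study's first report week began Monday
#'   2020-03-23).
#' @param base_volume Expected weekly retrieved posts per topic (scalar or
#'   named by topic id).
#' @param trajectory Named list of per-topic trajectories:
#'   `list(kind = "flat")`, `list(kind = "trend", rate = 0.1)` (weekly
#'   multiplicative growth), or `list(kind = "surge", week = 3, mult = 8)`.
#'   Topics default to flat.
#' @param question_rate Probability a relevant post poses a question.
#' @param fp_rate Fraction of retrieved posts that are planted false
#'   positives (keywords out of context).
#' @param fn_rate Fraction of relevant posts phrased without taxonomy
#'   keywords (must be < 0.5).
#' @param platform_mix Named probability vector over [post_platforms].
#' @param language_mix Named probability vector over the fixture languages.
#' @param engagement_meanlog,engagement_sdlog Log-normal engagement
#'   parameters (counts are floored to integers).
#' @param background_volume Expected weekly posts with only common words.
#' @param seed Integer seed; the corpus is a pure function of (spec, seed).
#' @return A `corpus_spec` object.
#' @export
corpus_spec <- function(fixture, weeks = 8, start = as.Date("2020-03-23"),
                        base_volume = 30, trajectory = list(),
                        question_rate = 0.3, fp_rate = 0.1, fn_rate = 0.15,
                        platform_mix = default_platform_mix(),
                        language_mix = c(en = 0.8, fr = 0.2),
                        engagement_meanlog = 1, engagement_sdlog = 1.5,
                        background_volume = 100, seed = 1) {
  stopifnot(inherits(fixture, "taxonomy_fixture"), weeks >= 1,
            question_rate >= 0, question_rate <= 1,
            fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate < 0.5,
            all(base_volume >= 0), background_volume >= 0)
  start <- lubridate::as_date(start)
  if (lubridate::wday(start, week_start = 1) != 1) {
    abort("start must be a Monday (weeks are ISO weeks)")
  }
  ids <- fixture$taxonomy$subcategories$id
  base <- if (length(base_volume) == 1) {
    setNames(rep(base_volume, length(ids)), ids)
  } else {
    stopifnot(all(ids %in% names(base_volume)))
    base_volume[ids]
  }
  bad_topics <- setdiff(names(trajectory), ids)
  if (length(bad_topics) > 0) {
    abort(paste0("trajectory for unknown topic(s): ",
                 paste(bad_topics, collapse = ", ")))
  }
  stopifnot(abs(sum(platform_mix) - 1) < 1e-6,
            all(names(platform_mix) %in% post_platforms),
            abs(sum(language_mix) - 1) < 1e-6,
            all(names(language_mix) %in% fixture$taxonomy$languages))
  structure(
    list(fixture = fixture, weeks = weeks, start = start, base_volume = base,
         trajectory = trajectory, question_rate = question_rate,
         fp_rate = fp_rate, fn_rate = fn_rate, platform_mix = platform_mix,
         language_mix = language_mix,
         engagement_meanlog = engagement_meanlog,
         engagement_sdlog = engagement_sdlog,
         background_volume = background_volume, seed = seed),
    class = "corpus_spec"
  )
}

trajectory_mult <- function(traj, week) {
  if (is.null(traj) || identical(traj$kind, "flat")) return(1)
  if (identical(traj$kind, "trend")) return((1 + traj$rate)^(week - 1))
  if (identical(traj$kind, "surge")) {
    return(if (week == traj$week) traj$mult else 1)
  }
  abort(sprintf("unknown trajectory kind '%s'", traj$kind))
}

# Question lead-ins that the question query recognizes.
question_openers <- list(
  en = c("why", "how", "what", "?"),
  fr = c("pourquoi", "comment", "est-ce que", "?")
)
common_lead <- c(en = "the", fr = "le")

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic given the spec (which carries the seed): running twice
#' yields byte-identical corpora. Each topic-week draws a Poisson retrieved
#' volume around `base_volume` times its trajectory multiplier; posts are
#' assembled from the fixture keyword bank (true positives), scripted
#' out-of-context keyword posts (false positives), synonym posts avoiding
#' all taxonomy keywords (false negatives), and background posts with only
#' common words.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `posts` (a post tibble), `truth` (per post:
#'   `topic`, `type` in tp/fp/fn/background, `is_relevant`, `retrievable`,
#'   `is_question`, `week`, `week_start`, `language`), and the `fixture`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  fix <- spec$fixture
  ids <- fix$taxonomy$subcategories$id
  langs <- names(spec$language_mix)

  withr::with_seed(spec$seed, {
    rows <- list()
    truth <- list()
    serial <- 0L

    draw_lang <- function() sample(langs, 1, prob = spec$language_mix)
    draw_platform <- function() {
      sample(names(spec$platform_mix), 1, prob = spec$platform_mix)
    }
    draw_engagement <- function() {
      e <- floor(rlnorm(4, meanlog = spec$engagement_meanlog -
                          c(0, 1, 3, 1.5),
                        sdlog = spec$engagement_sdlog))
      as.integer(e)
    }
    draw_time <- function(week) {
      spec$start + (week - 1) * 7 +
        lubridate::dseconds(floor(runif(1, 0, 7 * 86400 - 1)))
    }
    suffix <- function(lang) if (lang == "en") "" else lang

    emit <- function(topic, type, lang, week, text, is_question,
                     retrievable) {
      serial <<- serial + 1L
      e <- draw_engagement()
      ts <- draw_time(week)
      rows[[serial]] <<- list(
        id = sprintf("p%06d", serial), text = text, language = lang,
        timestamp = ts, platform = draw_platform(),
        likes = e[[1]], shares = e[[2]], poll_votes = e[[3]],
        reactions = e[[4]]
      )
      truth[[serial]] <<- list(
        id = sprintf("p%06d", serial), topic = topic, type = type,
        is_relevant = type %in% c("tp", "fn"),
        retrievable = retrievable, is_question = is_question,
        week = iso_week_key(ts), week_start = week_monday(ts),
        language = lang
      )
    }

    maybe_question <- function(text, lang) {
      opener <- sample(question_openers[[lang]], 1)
      if (opener == "?") paste(text, "?") else paste(opener, text)
    }

    for (ti in seq_along(ids)) {
      topic <- ids[[ti]]
      traj <- spec$trajectory[[topic]]
      for (w in seq_len(spec$weeks)) {
        lambda <- spec$base_volume[[topic]] * trajectory_mult(traj, w)
        v <- rpois(1, lambda)
        if (v == 0) next
        fp_flags <- rbinom(v, 1, spec$fp_rate) == 1
        for (j in seq_len(v)) {
          lang <- draw_lang()
          kw <- sample(c(fix$keywords[[topic]][[lang]],
                         paste(fix$phrases[[topic]][[lang]],
                               collapse = " ")), 1)
          if (fp_flags[[j]]) {
            text <- paste(common_lead[[lang]], "covid", kw,
                          "offtopic banter unrelated market chatter")
            emit(topic, "fp", lang, w, text, is_question = FALSE,
                 retrievable = TRUE)
          } else {
            is_q <- runif(1) < spec$question_rate
            text <- paste(common_lead[[lang]], "covid", kw,
                          "community update report")
            if (is_q) text <- maybe_question(text, lang)
            emit(topic, "tp", lang, w, text, is_question = is_q,
                 retrievable = TRUE)
            if (spec$fn_rate > 0 &&
                runif(1) < spec$fn_rate / (1 - spec$fn_rate)) {
              fn_lang <- draw_lang()
              fn_q <- runif(1) < spec$question_rate
              fn_text <- paste(common_lead[[fn_lang]], "covid",
                               fix$synonyms[[topic]][[fn_lang]],
                               "concern rising everywhere")
              if (fn_q) fn_text <- maybe_question(fn_text, fn_lang)
              emit(topic, "fn", fn_lang, w, fn_text, is_question = fn_q,
                   retrievable = FALSE)
            }
          }
        }
      }
    }

    if (spec$background_volume > 0) {
      for (w in seq_len(spec$weeks)) {
        b <- rpois(1, spec$background_volume)
        for (j in seq_len(b)) {
          lang <- draw_lang()
          text <- paste(common_lead[[lang]],
                        "weather sports chatter and other noise")
          emit(NA_character_, "background", lang, w, text,
               is_question = FALSE, retrievable = FALSE)
        }
      }
    }

    posts <- dplyr::bind_rows(rows)
    posts$timestamp <- lubridate::with_tz(posts$timestamp, "UTC")
    list(posts = posts, truth = dplyr::bind_rows(truth), fixture = fix)
  })
}

#' Simulate two human coders over ground-truth relevance
#'
#' Each coder reports the ground-truth relevance flipped independently with
#' probability `error_rate` (must be below 0.5). With zero error the coders
#' agree perfectly (kappa 1); with independent coin-flip coding kappa is
#' near 0.
#'
#' @param truth Ground-truth tibble (needs `id`, `is_relevant`, and
#'   optionally `topic`).
#' @param error_rate Per-item flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return A coded-item tibble (`id`, `subcategory`, `code`, `coder`) with
#'   coders `"A"` and `"B"`.
#' @export
simulate_coding <- function(truth, error_rate, seed) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  truth <- as_tibble(truth)
  n <- nrow(truth)
  subcat <- if ("topic" %in% names(truth)) {
    ifelse(is.na(truth$topic), "not_retrieved", truth$topic)
  } else {
    rep("not_retrieved", n)
  }
  withr::with_seed(seed, {
    flip_a <- rbinom(n, 1, error_rate) == 1
    flip_b <- rbinom(n, 1, error_rate) == 1
  })
  code_a <- as.integer(xor(truth$is_relevant, flip_a))
  code_b <- as.integer(xor(truth$is_relevant, flip_b))
  dplyr::bind_rows(
    tibble(id = truth$id, subcategory = subcat, code = code_a, coder = "A"),
    tibble(id = truth$id, subcategory = subcat, code = code_b, coder = "B")
  )
}

#' Score classification output against generator ground truth
#'
#' Counts, over relevant posts, retrieval hits of the true topic (TP) and
#' misses (FN), and over planted false positives, retrievals (FP), then
#' computes precision and recall. This is the bridge between the generator's
#' planted contamination rates and the validation metrics: precision should
#' approach `1 - fp_rate` and recall `1 - fn_rate`.
#'
#' @param records Classification records from [classify_corpus()].
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return A list: `tp`, `fp`, `fn`, `precision_pct`, `recall_pct`.
#' @export
evaluate_against_truth <- function(records, truth) {
  joined <- truth |>
    filter(.data$type %in% c("tp", "fp", "fn")) |>
    left_join(records |> select("post_id", "matched"),
              by = c(id = "post_id"))
  hit <- mapply(function(topic, matched) topic %in% matched,
                joined$topic, joined$matched)
  tp <- sum(joined$type %in% c("tp", "fn") & joined$is_relevant & hit)
  fp <- sum(joined$type == "fp" & hit)
  fn <- sum(joined$is_relevant & !hit)
  list(tp = tp, fp = fp, fn = fn,
       precision_pct = precision_rate(tp, fp),
       recall_pct = recall_rate(tp, fn))
}
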