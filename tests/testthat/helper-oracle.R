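# Independent oracles and generators for the query engine.
#
# oracle_eval() re-implements query semantics with different mechanics than
# eval_query(): phrase matching slides a window and compares pasted strings,
# and the connectives go through explicit truth-table lookups.

oracle_eval <- function(expr, tokens) {
  not_table <- c(`TRUE` = FALSE, `FALSE` = TRUE)
  switch(expr$kind,
    term = {
      if (length(tokens) == 0) return(FALSE)
      if (expr$wildcard) {
        any(vapply(tokens, function(t) {
          substr(t, 1, nchar(expr$term)) == expr$term
        }, logical(1)))
      } else {
        sum(tokens == expr$term) > 0
      }
    },
    phrase = {
      k <- length(expr$tokens)
      n <- length(tokens)
      if (n < k) return(FALSE)
      target <- paste(expr$tokens, collapse = "\x1f")
      windows <- vapply(seq_len(n - k + 1), function(i) {
        paste(tokens[i:(i + k - 1)], collapse = "\x1f")
      }, character(1))
      target %in% windows
    },
    and = {
      vals <- vapply(expr$children, oracle_eval, logical(1), tokens = tokens)
      sum(vals) == length(vals)
    },
    or = {
      vals <- vapply(expr$children, oracle_eval, logical(1), tokens = tokens)
      sum(vals) > 0
    },
    not = unname(not_table[as.character(oracle_eval(expr$children[[1]],
                                                    tokens))])
  )
}

# All query expressions with exactly `n` leaves drawn from `leaves`, binary
# AND/OR internal nodes; optionally a NOT wrapped around the root.
enumerate_exprs <- function(n_leaves, leaves, root_not = TRUE) {
  cache <- vector("list", n_leaves)
  gen <- function(n) {
    if (!is.null(cache[[n]])) return(cache[[n]])
    out <- if (n == 1) {
      leaves
    } else {
      res <- list()
      for (k in seq_len(n - 1)) {
        for (l in gen(k)) {
          for (r in gen(n - k)) {
            res[[length(res) + 1]] <- bq_and(l, r)
            res[[length(res) + 1]] <- bq_or(l, r)
          }
        }
      }
      res
    }
    cache[[n]] <<- out
    out
  }
  base <- unlist(lapply(seq_len(n_leaves), gen), recursive = FALSE)
  if (root_not) base <- c(base, lapply(base, bq_not))
  base
}

# All token documents of length <= max_len over an alphabet.
enumerate_docs <- function(alphabet, max_len) {
  docs <- list(character(0))
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    docs <- c(docs, lapply(seq_len(nrow(grid)), function(i) {
      unlist(grid[i, ], use.names = FALSE)
    }))
  }
  docs
}

# Random expression of depth <= max_depth over a word pool.
rand_expr <- function(max_depth, pool = c("covid", "vaccine", "flu", "mask",
                                          "où", "immunité", "long", "haul")) {
  rand_leaf <- function() {
    if (runif(1) < 0.25) {
      bq_phrase(sample(pool, sample(2:3, 1)))
    } else {
      bq_term(sample(pool, 1), wildcard = runif(1) < 0.2)
    }
  }
  build <- function(depth) {
    if (depth <= 0 || runif(1) < 0.3) return(rand_leaf())
    kind <- sample(c("and", "or", "not"), 1)
    if (kind == "not") return(bq_not(build(depth - 1)))
    children <- lapply(seq_len(sample(2:3, 1)), function(i) build(depth - 1))
    if (kind == "and") bq_and(children) else bq_or(children)
  }
  build(max_depth)
}

rand_doc <- function(pool = c("covid", "vaccine", "flu", "mask", "où",
                              "immunité", "long", "haul"),
                     max_len = 8) {
  n <- sample(0:max_len, 1)
  if (n == 0) character(0) else sample(pool, n, replace = TRUE)
}

# Tiny hand-built taxonomy used across classifier/surveillance tests.
toy_taxonomy <- function() {
  taxonomy(
    categories = c("treatment", "illness"),
    subcategories = tibble::tibble(
      id = c("vaccines", "symptoms", "transmission"),
      category = c("treatment", "illness", "illness"),
      name = c("Vaccines", "Symptoms", "Transmission"),
      query_en = c(
        "covid AND vaccin*",
        'covid AND (fever OR cough OR "loss of smell")',
        "covid AND (transmission OR airborne OR spread)"
      ),
      query_fr = c(
        "covid AND vaccin*",
        "covid AND (fièvre OR toux)",
        "covid AND (transmission OR aérosol)"
      )
    )
  )
}

toy_posts <- function(texts, language = "en", start = "2020-03-23",
                      platform = "twitter", likes = 0L) {
  n <- length(texts)
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * seq_len(n)
  posts_tibble(
    id = sprintf("post%03d", seq_len(n)), text = texts,
    language = rep_len(language, n), timestamp = ts,
    platform = rep_len(platform, n), likes = rep_len(likes, n)
  )
}
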