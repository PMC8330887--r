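# infodemic

Taxonomy-based social listening for public-health emergencies: detect
potential **information voids** — topics where demand for information
(volume, growth, questions) outstrips the supply of credible content — in
public social-media conversations, and validate how well the keyword
searches retrieve what they are meant to retrieve.

The package is aimed at infodemic-management and risk-communication teams
(and at researchers studying infoveillance methods) who need a weekly,
reproducible answer to: *which topics should we address first, and how much
can we trust the retrieval behind that answer?*

## What it implements

**Classification.** Public posts (English/French) are matched against a
taxonomy of keyword-defined subcategory searches — the reference design has
5 categories × 35 subcategories — written in a small Boolean query language
(terms, quoted phrases, `AND`/`OR`/`NOT`, parentheses, trailing `*`
wildcard; whole-token, casefolded, accent-preserving matching). Each post is
also tested against a *question* query (interrogative words, `?`,
auxiliary–subject inversions, French `est-ce que` / `peut-on` forms) and a
*common-word baseline* query that sizes the total conversation.

**Surveillance.** Per subcategory and ISO week: volume, question share,
engagement, and velocity

```
velocity = (V_t − V_{t−1}) / V_{t−1} × 100%
```

with undefined (never infinite) values on zero-volume predecessors. Up to
10 topics per week are flagged as candidate information voids when velocity
≥ +50%, or question share / engagement strictly exceed their cross-topic
80th percentiles (configurable; always recorded in the report).

**Validation.** The retrieval-quality protocol: per-subcategory precision
`TP/(TP+FP)` from coded retrieved samples, recall `TP/(TP+FN)` from a coded
"not retrieved" sample, `F1` and the precision-weighted `F0.5`, Cohen's
kappa for intercoder reliability, largest-remainder downweighting of
confusion counts, and seeded coding-sample construction.

**Synthetic corpora.** A seeded generator with ground-truth labels (topic,
relevance, question status) emulating weekly Poisson volumes with plantable
surges, planted false positives/negatives with exact expected
precision/recall, a Twitter-dominant platform mix (~87%), and heavy-tailed
engagement — so the whole pipeline is testable offline.

## Worked example

```r
library(infodemic)

tax <- load_taxonomy(system.file("extdata", "example_taxonomy.yaml",
                                 package = "infodemic"))
tax
#> <taxonomy> 2 categories, 3 subcategories, languages: en, fr

posts <- posts_tibble(
  id = sprintf("p%02d", 1:6),
  text = c("Do the covid vaccines even work?",
           "covid jab booked for tomorrow",
           "long covid fever and cough again",
           "pourquoi le vaccin covid est-il si lent",
           "weather is lovely today",
           "covid spreads by airborne droplets, experts say"),
  language = c("en", "en", "en", "fr", "en", "en"),
  timestamp = c("2020-03-23T09:00:00Z", "2020-03-24T10:00:00Z",
                "2020-03-31T11:00:00Z", "2020-03-31T12:00:00Z",
                "2020-04-01T08:00:00Z", "2020-04-01T13:00:00Z"),
  platform = c("twitter", "twitter", "reddit", "twitter", "blog", "twitter"),
  likes = c(12L, 2L, 5L, 7L, 0L, 40L))

res <- classify_corpus(posts, tax)
res$records[, c("post_id", "matched", "is_question", "week")]
#> 1 p01     <chr [1]> TRUE        2020-W13
#> 2 p02     <chr [1]> FALSE       2020-W13
#> 3 p03     <chr [1]> FALSE       2020-W14
#> 4 p04     <chr [1]> TRUE        2020-W14
#> 5 p05     <chr [0]> FALSE       2020-W14
#> 6 p06     <chr [1]> FALSE       2020-W14
```

Post p01 matched the vaccines search (`covid AND (vaccine OR vaccin* ...)`)
and was detected as a question (sentence-initial auxiliary *do* and the
literal `?`); the French post p04 matched via `vaccin*` with *pourquoi*
and the `est-il` inversion marking it a question; the off-topic post p05
matched nothing. Weekly aggregation then yields per-topic series:

```r
stats <- weekly_aggregate(res$records, subcategories = tax$subcategories$id)
stats[stats$volume > 0, c("subcategory", "week", "volume",
                          "question_volume", "velocity")]
#> 1 illness-symptoms     2020-W14      1               0       NA
#> 2 illness-transmission 2020-W14      1               0       NA
#> 3 treatment-vaccines   2020-W13      2               1       NA
#> 4 treatment-vaccines   2020-W14      1               1      -50
```

Vaccines fell from 2 to 1 posts week-on-week: velocity −50%. First observed
weeks have undefined velocity (`NA`), not a number. On real data,
`detect_signals(stats, week)` would rank and flag up to 10 topics.

The validation side reproduces published-style arithmetic directly from a
confusion table:

```r
validation_report(confusion_counts(tp = 875, fp = 125, fn = 304, tn = 696))
#> <validation_report> precision 88%, recall 74%, F1 0.80, F0.5 0.84,
#>   not-retrieved irrelevant 70%
```

i.e. 74% of relevant content was retrieved, 70% of the not-retrieved sample
was correctly left out, and the precision-weighted F0.5 (0.84) exceeds F1
(0.80) because precision exceeds recall — the preferred regime when
misclassified retrieved posts are costlier than missed ones.

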