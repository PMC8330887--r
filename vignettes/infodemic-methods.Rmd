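---
title: "Detecting information voids in social-media conversations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting information voids in social-media conversations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemic)
```

## The problem

During an acute public-health event, online conversation grows faster than
credible information can be produced. Topics where demand for information is
high (many posts, rapid growth, many questions) but the supply of verified
content is low — *information voids* — are where rumor and misleading
content take hold first. A social-listening pipeline that surfaces such
topics weekly gives a health authority time to respond before a void fills
with speculation.

`infodemic` implements such a pipeline end to end:

1. a **taxonomy** of keyword-defined topic searches (the reference design
   uses 5 top-level categories — the cause, the illness, the treatment, the
   interventions, and the meta-conversation about information itself — split
   into 35 subcategories), each expressed as a Boolean search string per
   language;
2. a **classifier** that pairs every public post with every subcategory
   search, a language-level *question* query, and a *common-word baseline*
   query that estimates the size of the whole conversation;
3. weekly **surveillance** statistics per topic — volume, question share,
   engagement, and *velocity* — with rule-based flagging of candidate
   information voids;
4. a **validation** module implementing the retrieval-quality protocol
   (precision, recall, F1/F0.5, Cohen's kappa);
5. a seeded **synthetic-corpus generator** with ground truth, so that every
   stage is testable without any platform access.

## The query language

Vendor listening platforms each have their own Boolean dialect; none is
standardized. The package fixes a minimal, fully specified grammar: bare
terms, quoted phrases, `AND`, `OR`, unary `NOT`, parentheses, and an
optional trailing `*` wildcard for prefix matching (pandemic vocabulary
mutates: `vaccin*` covers *vaccine, vaccines, vaccination, vaccin,
vaccinul*). `AND` binds tighter than `OR`; adjacency is an implicit `AND`.
Three deliberate choices:

* **Operators are uppercase-only.** The common-word baseline queries must be
  able to use *and* and *or* as search terms; casefolded operators would
  make those unwritable.
* **Whole-token matching.** A term matches a complete token, never a
  substring, so `flu` does not fire on *influence*. Prefix matching exists
  only behind the explicit wildcard.
* **Casefolded but accent-preserving.** French *où* (an interrogative) and
  *ou* (a baseline conjunction) must remain distinct.

Matching operates on the same tokens the classifier produces: casefolded
word tokens with intra-word hyphens kept (`covid-19`, `est-ce`), the French
apostrophe elision split so the clitic keeps its apostrophe (`l'immunité`
→ `l'`, `immunité`), and `?` retained as a sentinel token.

```{r query}
q <- parse_query('covid AND (vaccine OR vaccination) NOT influenza')
eval_query(q, tokenize("COVID vaccine rollout today"))
eval_query(q, tokenize("covid vaccine vs influenza vaccine"))
```

The evaluator is verified two independent ways in the test suite: against a
brute-force oracle (truth tables for the connectives, sliding-window
comparison for phrases) over *every* expression of up to 4 leaves crossed
with every document of up to 6 tokens over a small alphabet, and by a
serialize-and-reparse identity on 1,000 random expression trees.

## Question and baseline detection

A post "poses a question" if any of: a literal `?`; an interrogative word
(*what/why/how/...*; *pourquoi/comment/où/...*); the French phrase *est-ce
que*; an auxiliary–pronoun inversion (*are they*, *should we*) or a
sentence-initial auxiliary (*do vaccines work*); or a French hyphenated
inversion (*peut-on*). Both token patterns and the `?` character are
included because an interrogative post need not carry punctuation. This is
a deliberately recall-oriented heuristic: occasional declarative false
positives (e.g. *is it what it is*) are acceptable because question volume
is used as a relative weekly signal, not an absolute count.

The baseline query estimates total conversation volume from posts containing
any highly frequent function word (*the, and, or, I*; *le, la, ou, et*).
Taxonomy-matched volume divided by baseline volume (`relevant_share()`)
contextualizes how much of the conversation the taxonomy covers; in the
global study setting this was on the order of 3%.

## Weekly statistics and signal flagging

Weeks are ISO-8601 weeks (Monday start, UTC) — the reporting cadence of the
original workflow, whose first report week began Monday 2020-03-23. For each
(subcategory, week): volume, question volume and share, summed engagement
(the unweighted sum of likes, shares, poll votes and reactions — the kinds
are reported without weights, so none are invented), and velocity

$$\text{velocity} = \frac{V_t - V_{t-1}}{V_{t-1}} \times 100\%$$

Velocity is **undefined** (not infinite) when the previous week had zero
volume; such topics can still be flagged through a separate *new topic*
trigger when their volume exceeds the cross-topic median. Velocity averages
over a series exclude undefined weeks.

The study flags "up to 10 topics with high velocity and/or a large
proportion of posts expressing a question and/or high engagement" — but
never quantifies *high*, which was an analyst judgment. Reproducibility
requires explicit defaults, so `signal_config()` fixes: velocity ≥ +50%,
question share strictly above the cross-topic 80th percentile, engagement
strictly above its 80th percentile, at most 10 flags. Strict quantile
exceedance means a week in which every topic is identical produces no flags.
Flags are scored by the largest standardized exceedance among their
triggers; ties break by volume, then lexicographic id — so the output is
invariant to input row order. All thresholds are printed in every report.

Trend summaries (`positive_velocity_weeks()`, `avg_weekly_increase()`,
`longest_positive_streak()`, `monthly_top_topics()`) reproduce the style of
the study's long-run tables; monthly ties are broken lexicographically and
marked rather than silently dropped.

## Validation protocol

Retrieval quality is validated by human coding: a per-subcategory sample of
retrieved posts coded relevant/irrelevant gives **precision**
(`TP/(TP+FP)`); a sample of posts that mention the pandemic but match no
taxonomy search, coded the same way, gives the false negatives for
**recall** (`TP/(TP+FN)`). `F1` and `F0.5` combine them, with `F0.5`
preferred: for signal detection it is costlier to pollute a topic with
irrelevant posts than to miss some relevant ones, so precision is weighted
over recall (and `F0.5 > F1` exactly when precision > recall — a tested
invariant). Intercoder reliability on spot-check subsamples uses binary
Cohen's kappa; weighted or multi-coder kappas are out of scope.

Rounding follows the publication convention exactly: per-subcategory
precision to 1 decimal place, corpus averages as unweighted means over
those 1-dp rates rounded to whole percent (this — not pooling TP/FP — is
what reproduces the published 82% initial and 87% retest averages from the
printed per-search counts), F-scores and kappa to 2 decimals, and the
below-target comparison is strict (a 71.7% search does not fall below a 70%
target). `downweight_counts()` rescales the retrieved sample to the size of
the not-retrieved sample with largest-remainder rounding, so the combined
confusion table has exact integer margins.

One published inconsistency is handled deliberately: the spot-check kappa
for the precision sample is printed as 0.81 alongside agreement values
(0.95, 0.76) that actually yield 0.79 — presumably rounded inputs. The
implementation always computes kappa from its inputs and never forces a
printed value. Similarly, "30 posts per search, 1,500 in total" is not
consistent with 35 searches, so the sampler takes explicit size and
fraction parameters instead of hard-coding either number.

## What the generator emulates — and what it does not

The study's keyword lists are not public and its corpus (about a billion
posts via a commercial aggregator) is not reproducible at desk scale, so
the package ships a generator whose outputs have *known ground truth*:

* **Topic structure**: a taxonomy fixture with the 5 × 35 reference shape by
  default, disjoint keyword banks per subcategory, plus deliberately shared
  "ambiguous" keywords across topic pairs to exercise multi-label matching.
* **Weekly dynamics**: per-topic Poisson volumes around a base level
  (default 25–40 posts/week per topic in the shipped tests — large enough
  for stable velocity estimates, small enough that 50-corpus experiments
  run in minutes) with flat, trend, or surge trajectories. Poisson noise is
  intentional: the signal detector must recover a planted 8× surge against
  sampling variation, not against deterministic steps.
* **Contamination with exact expectations**: each retrieved post is a false
  positive with probability `fp_rate` (keywords in scripted irrelevant
  context), so expected precision is `1 − fp_rate`; each true positive
  spawns an unretrievable relevant companion (synonym phrasing, no taxonomy
  keyword) with odds `fn_rate/(1 − fn_rate)`, so expected recall is
  `1 − fn_rate`. The end-to-end acceptance test recovers both rates within
  binomial 95% tolerance on a ~2,000-post corpus.
* **Platform and engagement shape**: the published platform shares
  (Twitter-dominant at 87%; YouTube listed as a source but with no printed
  share, assigned 0 and normalized) and discrete log-normal engagement —
  heavy tails are what make an "high engagement" trigger meaningful.
* **Questions**: relevant posts become questions at a configurable rate by
  prepending interrogative openers or appending `?` — forms the question
  detector provably recognizes.

The generator does **not** emulate: linguistic realism (templates exercise
the token matcher only), cross-platform reposting (duplicates are treated
as distinct posts, as the study's "unique posts" phrasing implies),
language identification (the language tag is an input), topic drift within
a week, or coder bias beyond symmetric random flips. A green pipeline on
synthetic corpora therefore demonstrates *mechanical and statistical*
correctness — formulas, conservation, ranking, recovery of planted effects
under noise — not retrieval quality on real platform text, which is
exactly why the human-coding validation protocol exists.

## Numerical and degenerate-input choices

* Zero-denominator velocity, precision, recall, F-scores and kappa raise
  errors or return NA markers as documented — never `Inf`/`NaN`.
* Quantile triggers use strict exceedance; the velocity threshold is
  inclusive (`>=`), matching its phrasing as a floor.
* Signal scores standardize each trigger's exceedance by the cross-topic
  standard deviation of that metric (falling back to 1 when degenerate), so
  triggers on different scales are comparable; ranking ties break by
  volume then id.
* Rounding of published-style percentages uses round-half-up (the table
  convention), not banker's rounding.
* Corpus readers are lenient by default (skip and warn; last-wins on
  duplicate ids, since aggregator exports commonly contain duplicates) and
  strict on request (first problem aborts with its line number).
* All randomness — generator, coding simulation, sampling — flows through
  explicit integer seeds; rerunning any command with the same inputs,
  configuration and seed reproduces every output file byte for byte.

## Problem sizes used in the shipped checks

The acceptance suite runs, per invocation: the published-table arithmetic
(instantaneous); the evaluator-vs-oracle cross-check over all ≤4-leaf
expressions × ≤6-token documents (~880k comparisons); 1,000 random
parser round-trips; 50 seeded corpora (8 topics × 5 weeks, base volume 25)
for surge recovery; and one ~2,500-post corpus (10 topics × 5 weeks, base
volume 40) for precision/recall recovery. These sizes were chosen so the
statistical checks have enough power to fail loudly (binomial tolerances of
a few percentage points) while a full run stays in the minutes range on a
single core.
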