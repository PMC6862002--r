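---
title: "Methods: credibility scoring and exposure estimation for shared health pages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: credibility scoring and exposure estimation for shared health pages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxcred)
```

## The problem and the model

Health misinformation surveillance on social media needs a page-level
measure that is broader than true/false: whether a shared Web page uses
scientific evidence, reports uncertainty, avoids exaggeration, provides
context, is readable, and discloses its sponsorship. `vaxcred` operationalizes
a 7-item credibility checklist: each page receives 7 binary judgments
(criterion satisfied or not), their sum is the **credibility score** (0–7),
and scores are banded **low** (0–2), **medium** (3–4) and **high** (5–7).
The bands are fixed in `credibility_band()` and are not configurable; they
partition 0..7 and are monotone in the score.

Manual appraisal does not scale to the hundreds of thousands of pages shared
on a platform, so the package trains one binary text classifier per
criterion on tf-idf features and combines the **best family per criterion**
into an ensemble that scores unseen pages. Two classical families are
compared:

* a margin-based classifier (linear-kernel SVM, `C = 100`, `gamma = 1`), and
* a tree ensemble (random forest, 10 trees, Gini impurity),

each evaluated by stratified 10-fold cross-validation, reporting mean and SD
of F1 (criterion-satisfied class) and accuracy. Selection per criterion is by
mean F1; exact ties go to the tree ensemble, which is the stronger family on
most criteria in this design. Deep sequence models are deliberately out of
scope: they need pretrained language-model weights and GPU-scale fine-tuning,
and offer no desk-scale mechanism to verify.

Downstream, the score feeds two analyses:

* **Term informativeness** — for each vocabulary term, a 2×2 table of
  document-level presence in low-band versus other pages, tested with a
  two-sided Fisher exact test and summarized with an odds ratio.
* **Exposure and sharer subpopulations** — from a tweet log, the
  **potential exposure** of a page is the sum of the posting users' follower
  counts over all tweets *and* retweets linking it (an upper bound on
  audience; overlapping audiences are deliberately not deduplicated), and a
  follower network restricted to users who shared at least two scored pages
  supports community and assortativity analysis of who shares low-credibility
  material.

## Corpus filters

`run_ingest()` applies, in order: text cleaning (whitespace collapse,
removal of characters outside letters/digits/basic punctuation — emoticons
and other symbols drop out), a language filter, removal of empty pages
(modeling broken or unavailable links, since the package consumes already
fetched text), a 300-word minimum length filter, and near-duplicate removal.
Each stage's count is recorded in an attrition report, which is monotonically
non-increasing by construction.

Decisions where the procedure is genuinely open:

* **"Most of the text equivalent"** is operationalized as word 5-shingle
  Jaccard similarity ≥ 0.8, transitively grouped; within a duplicate group
  the page with the greatest word count is retained, ties broken by the
  lexicographically smallest id. Both the threshold and shingle width are
  arguments. 5-shingles with a 0.8 threshold is standard near-duplicate
  territory: independently written pages on the same topic share vocabulary
  but almost no 5-word runs.
* **"Fewer than 300 words"** keeps a page iff its whitespace word count on
  the cleaned text is ≥ 300; the original block structure of the scraped
  page is not recoverable from stored text, so the count is over the full
  cleaned text.
* The **language detector** is pluggable (any function from a string to
  `english` / `non-english` / `undetermined`). The default is a two-part
  heuristic: texts whose letters are mostly non-Latin are non-English;
  otherwise the fraction of tokens that are common English function words
  must reach 0.1. Detector failures mark a page `undetermined`, which is
  excluded. A trained language identifier would be better on real multilingual
  crawls; the heuristic's contract is what the pipeline depends on.

## Feature construction

Tokenization is lowercase, whitespace-split, with punctuation stripped from
tokens; the same tokenizer serves word counting, features, and term tests so
the three stay consistent. Stop words (a compact SMART-style English list,
replaceable) and terms with total corpus frequency < 2 are pruned. Features
are tf-idf with smoothed idf

$$\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1,$$

and **L1 row normalization**; `max_df = 1` (the default) keeps terms present
in every document. The idf smoothing constant is not dictated by the design
being followed, so it is fixed and documented here for reproducibility; any
smooth variant would serve. Featurization is refit on each training fold
during cross-validation — vocabulary, document frequencies and idf are
computed from training-fold documents only, so no test-fold information
leaks into the features.

F1 is computed on the criterion-satisfied class. When a test fold has no
actual and no predicted positives the fold's F1 is undefined and excluded
from the mean rather than silently counted as 0 or 1; with stratified folds
this is rare even for the rarest criteria. Stratified folds use a fixed
seed (default 42) offset per criterion.

## The synthetic study

No labeled page sample, tweet archive or follower network is distributed
with the problem, so the package carries a generator whose defaults *are*
the study conditions every statistical claim is tested under.

**Corpus** (`corpus_spec()` / `generate_corpus()`): each page draws 7
independent Bernoulli criterion labels with prevalences
`(0.5, 0.35, 0.15, 0.55, 0.45, 0.6, 0.1)` — substantial imbalance with two
rare criteria (3 and 7), mirroring a labeled sample in which the
margin-based family tends to win exactly on the rare criteria. The exact
empirical proportions behind that imbalance are not published numerically,
so the defaults are configurable and are chosen once to reproduce the
qualitative shape. Text is a unigram bag of words — matching the (1,1)
n-gram feature space — mixing three layers: 35% common English function
words (so stop-word-based heuristics behave realistically), a Zipf-weighted
200-term background shared by all pages, and 30% criterion-conditional
signal terms. A signal token picks one of the 7 criteria uniformly and emits
a term from that criterion's "satisfied" set with probability equal to the
**signal contrast** (default 0.95) when the label is 1, from the
"unsatisfied" set otherwise, mirrored for label 0. At contrast 0.5 the text
carries no information about the labels; near 1 the task is cleanly
separable. Page lengths are uniform on 300–600 words so generated pages
pass the length filter. What this generator does *not* emulate — topic
drift, correlated criteria, boilerplate, multilingual noise, label error —
bounds what passing tests show about real crawls: they demonstrate that the
machinery recovers planted structure, not that real-world F1 will be high.

**Noise injection** (`inject_filter_noise()`) appends near-duplicates
(1% of word positions resampled, keeping expected 5-shingle Jaccard ≈ 0.9,
safely above the 0.8 threshold — at 5% resampling the expected Jaccard falls
to ≈ 0.63 and injected duplicates would *not* count as duplicates), short
English pages, and non-Latin-script pages, with exact bookkeeping so
attrition tests can assert stage counts to the page.

**Social structure** (`social_spec()` / `generate_social()`): users are
split into communities; the directed follower graph is a stochastic block
model (within-community edge probability ≥ between, default 0.05 / 0.005);
follower counts follow a discrete power law with exponent 2.1 capped at the
population size, reproducing heavy-tailed exposure distributions
qualitatively. Each posting slot is a retweet of a uniformly chosen earlier
original with probability `retweet_prob`, else an original tweet of a page
drawn via the author community's band bias. A retweet record carries the
retweeter's own follower count, consistent with exposure defined as a sum
over all tweets and retweets of the posting user's followers.

## Numerical and procedural choices

* **Fisher exact test**: implemented by hypergeometric enumeration with the
  probability-mass two-sided rule (sum of all tables, under fixed margins,
  whose probability is ≤ the observed table's, with a `1 + 1e-7` tolerance
  against floating-point ties); degenerate margins give p = 1. The test
  suite checks it against an independent binomial-coefficient enumeration
  and against `stats::fisher.test`. The sidedness convention is a choice;
  the probability-mass rule is the common default in statistical software.
* **Odds ratio**: `(ad)/(bc)`, `Inf` when only the denominator vanishes,
  and `NA` with a warning when both cross products are zero.
* **Multiple testing**: term ranking reports raw p-values by default, with
  Benjamini–Hochberg available but off — the analysis this mirrors reported
  uncorrected exact tests.
* **Fleiss' kappa**: mean item agreement versus chance agreement from
  category marginals; undefined (raised as an error) when all ratings fall
  in one category. The CI is a seeded percentile bootstrap over items
  (default 1000 replicates) — distribution-free and honest at the small
  item counts typical of duplicate-appraisal subsets; replicates whose
  resample is single-category are dropped.
* **Per-user profiles** count each distinct page once regardless of how
  often a user tweeted it (configurable via `distinct_pages = FALSE`);
  "sharing links to one or more Web pages" does not resolve repeats, so the
  distinct-page reading is the default and the other is available.
* **Sharer categories**: high-sharer iff ≥ 2 high-band pages and 0 low-band;
  low-sharer iff ≥ 2 low-band and 0 high-band; otherwise other — exclusive
  and exhaustive by construction.
* **Network construction** applies the ≥ 2-shared-pages filter first, then
  keeps the largest *weakly* connected component (the order and the
  connectivity notion are unstated in the design being followed; weak
  connectivity is the natural choice for a follower graph viewed as a
  contact structure). Equal-sized largest components tie-break to the one
  containing the lexicographically smallest user id, keeping the operation
  deterministic.
* **Percentages** are reported to 2 decimals throughout
  (`percentage_share()`), so band shares sum to 100 within ±0.02.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run the synthetic study at sizes
chosen to make the statistical assertions sharp while staying desk-scale:
2,000 pages (10-fold CV, both families, all 7 criteria) for parameter
recovery with a 500-page fresh sample for ensemble band accuracy; 200 pages
× 200 terms for Fisher type-I calibration against a 99% binomial band around
0.05; ~11,000 tweets from 2,500 users for exposure conservation; and
150-user two-community graphs for homophily, assortativity and community
recovery (adjusted Rand index against the planted partition). Fixed seeds
make every run reproducible; the acceptance script threads a single
command-line seed through all of them.

## Known limitations

* The synthetic corpus is far more separable than real Web text; the
  recovery results certify the pipeline, not field performance.
* The stop-word-coverage language heuristic will misclassify
  Latin-script non-English text with many English loanwords.
* Near-duplicate detection is exact pairwise Jaccard over shingle sets with
  an inverted-index candidate filter — fine to tens of thousands of pages,
  not engineered for millions (minhashing would be the next step).
* Potential exposure is an upper bound by design: follower audiences
  overlap and no deduplication across tweets is attempted.
* The ensemble predicts criteria independently; correlations between
  criteria are not modeled.
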