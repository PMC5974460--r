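---
title: "Mining unmet information needs from health-forum text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining unmet information needs from health-forum text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needgap)
```

## The problem

Peer-to-peer health forums are a record of the questions patients actually
ask, in their own words, over years. For a population such as breast cancer
survivors, mining those questions answers two things that surveys answer
poorly: *what* information people feel they lack, and *whether the education
materials they are routinely given cover it*. `needgap` implements that
pipeline end to end:

1. a **data model** for forum corpora (conversation → post → sentence-type
   unit) with a ten-category information taxonomy and a binary
   "has information need" (HASN) flag;
2. **rule induction** of minimal bigram patterns over a question-cue
   vocabulary, for bootstrapping need detection before annotated data exist;
3. **one-vs-rest sentence classifiers** (multinomial naive Bayes, linear
   SVM, random forest) over word, bigram, local-context, topic-model and
   word-embedding features, with 10-fold cross-validation and cross-forum
   transfer evaluation;
4. **concept profiling**: frequency-ranked concepts per category through a
   pluggable term→concept lexicon;
5. **gap assessment**: tf-idf query construction from need sentences
   (with referential resolution), Okapi BM25 retrieval over indexed
   education pages, and agreement/coverage statistics over rater verdicts.

Because real survivor-forum corpora and clinic brochures are not
redistributable, the package ships a **synthetic-forum generator** that
reproduces the statistical structure the analysis assumes. Every stage is
therefore testable offline, and the generator's gold labels make end-to-end
recovery checks possible that no observational corpus supports.

## The data model

A corpus is a flat ordered tibble of sentences plus a dialect tag. Two
annotation dialects exist, mirroring how such data get coded in practice:
the **MC dialect** gives each sentence exactly one category, using a
`multiple` label for mixed sentences; the **CSN dialect** allows up to two
labels and drops `multiple`. The taxonomy's content categories are
`medical`, `resource`, `social`, `psychological`, `background`, `wellness`,
`physical`, plus `previous` (the sentence's topic requires resolving a
reference to an earlier sentence) and `other`.

Sentence segmentation is rule-based — boundaries at `.`, `!`, `?` and
newlines, with a packaged abbreviation list so "Dr." or "e.g." never split —
and the tokenizer lowercases, splits on whitespace and strips edge
punctuation while keeping internal apostrophes and hyphens. Both are
deterministic, and tokens are *recomputed* from text on every read, so the
recomputability invariant cannot drift. Descriptive statistics use the
sample (n−1) SD convention; a category fraction gives each sentence weight
1 for each of its labels over the sentence total, so two-label corpora can
sum above 1 — that matches how per-category counts are tabulated against a
sentence total.

## The synthetic generator

`mc_profile()` and `csn_profile()` encode the descriptive profiles of the
two study corpora: 65 conversations / 6.35 (SD 4.42) sentences per post /
14.04 (SD 6.30) words per sentence with ~5.7% HASN prevalence for MC; 11.52
(SD 5.29) sentences per post / 13.97 (SD 5.30) words per sentence, two-label
annotation and ~8.7% prevalence for CSN. Design choices worth knowing:

* **Length distributions** are truncated rounded normals (minimum 1); only
  means and SDs are published, and a truncated normal is the least
  structured choice that honours them. Truncation at 1 lifts the realised
  words-per-sentence mean by ≈ 0.05, well inside the stochastic tolerances
  the tests use.
* **Posts per conversation** is not published for either corpus; it is set
  so that expected corpus size matches the published sentence totals
  (≈ 4.7 posts/conversation for MC at 65 conversations; ≈ 2 for CSN at 92).
* **Category mixtures and per-category need rates** come from the published
  per-category count tables. The MC per-category counts sum to 1942 of 1943
  sentences (printed rounding), so the vector is renormalised. The CSN
  two-label rate of 0.10 is derived from the same table: category counts
  sum to 2473 over 2246 sentences.
* **Sentence realisation** uses category-exclusive word banks plus shared
  fillers. Need sentences open with a wh-question or an indirect
  first-person statement cue ("i was wondering about …") with equal
  probability, exercising the definition of HASN as covering direct *and*
  implicit questions. Referential sentences contain a referring cue
  (this/that/it) and no bank word.
* **`previous_follow_rate`** is the probability that a "previous"-category
  sentence directly following a need sentence restates that need (the
  duplicate pattern removed at query construction). Its default 0.3 is
  derived from the study arithmetic: 196 need sentences yielded 136 queries
  after duplicate removal. The knob conditions the HASN flag on the
  neighbour rather than inserting extra sentences, so the category mixture
  remains exactly the configured one at any setting.
* **`label_autocorrelation`** optionally makes a sentence repeat its
  predecessor's category with the given probability. The marginal category
  distribution is unchanged for any value; the default is 0 so that the
  mixture contract is exact and independent draws make the goodness-of-fit
  property testable. Positive values create the topical runs that make
  neighbour-label context features informative, and the context-ablation
  test generates its corpora that way.
* One master seed derives three independent sub-stream seeds (corpus,
  pages, raters), so stages can be re-run in isolation and byte-identical
  artifacts are reproducible from a config alone.

The education-page generator plants category word banks into pages under a
`coverage_fraction` dial: exactly `round(c × n_topics)` topics receive at
least one page with ≥ 3 of their exclusive words; uncovered topics appear
nowhere. Because banks are category-exclusive and disjoint from fillers,
gold coverage is unambiguous. Simulated raters mark truly covering pages
relevant with a configurable sensitivity and non-covering pages with a
false-positive rate.

**What the generator does not emulate:** natural language (sentences are
bag-of-template realisations), author identity and thread dynamics beyond
post order, misspellings, vocabulary drift, or the lexical ambiguity of
real forum prose. Classifier scores on synthetic corpora are therefore
*upper bounds* that validate the machinery — leakage-free feature
construction, fold handling, metric arithmetic — not forecasts of accuracy
on real text, where published F-scores for comparable pipelines sit in the
0.6–0.9 band depending on category support.

## Rule induction for need detection

Before annotation exists, need sentences can be screened by bigram patterns
over a cue vocabulary V (wh-words, auxiliaries, pronouns, request words such
as *wondering*, *trouble*, *anyone*). The induction loop processes positives
in corpus order and, for each positive not already matched, accepts the
smallest set of its cue bigrams contained in no negative example. Two
choices the loop's specification leaves open are fixed for reproducibility:
subsets are searched in increasing cardinality and, within a cardinality,
lexicographically over bigrams ordered by sentence position; and the search
caps at four bigrams (larger patterns overfit and the search is
combinatorial), recording the example as unseparable beyond that. The test
suite verifies the loop against an exhaustive brute-force subset search,
and verifies minimality, train-set consistency (no accepted pattern matches
any negative) and monotonicity under added negatives.

## Classifiers and features

* **Metrics.** Folds are stratified; confusion counts are pooled across
  folds and positive-class precision/recall/F computed from the pooled
  counts (micro over folds). The averaging convention and the positive-class
  choice are the natural ones for one-vs-rest with rare categories, where
  per-fold macro averages are unstable.
* **Leakage.** Term manifests (words/bigrams with training frequency
  ≥ `min_term_count`, default 2) and topic models are refitted per fold on
  the training portion only. Local-context features use gold neighbour
  labels — the offline-evaluation convention; a production system cannot do
  that, so `context_source = "predicted"` with `classify_sequential()`
  decodes left-to-right using already-predicted labels and zeroed
  next-sentence bits.
* **Learners.** Random forest: 100 trees, default feature subsampling,
  fixed seed (ranger). Linear SVM: C = 1, no scaling (e1071). Naive Bayes:
  multinomial on counts with Laplace smoothing — written in-package because
  no installed implementation of the multinomial variant exists; it is a
  ten-line model and is exercised against hand-computable cases.
* **Topic features.** A collapsed Gibbs LDA sampler (also in-package for
  the same reason) with symmetric priors α = 50/T, β = 0.01; defaults T = 50
  topics, 15 reported words per topic, 500 sweeps. A sentence's feature is
  the fraction of its tokens assigned to each topic, so out-of-vocabulary
  tokens dilute towards zero and an empty sentence gets a zero block.
* **Embeddings.** Any plain-text `word v1 … vD` table is accepted; the
  sentence feature is the elementwise mean over in-table tokens (zero
  vector if none). A 50-word, 5-dimensional toy table ships for tests; no
  pretrained vectors are downloaded.
* The trained class list covers all nine non-`multiple` categories
  including `resource`; `multiple`-labelled sentences (MC dialect) are
  excluded from both positives and negatives of every one-vs-rest
  classifier, since they are known to belong to more than one class. A
  two-label CSN sentence counts as a positive for each of its labels.
* Whether published word counts include punctuation tokens is unstated;
  this tokenizer strips edge punctuation, so counts here are content-token
  counts.

## Concept profiling

A pluggable lexicon (CSV `term,concept`, 1–3-token surface terms, greedy
longest-match, non-overlapping) stands in for a medical concept tagger, so
the ranking pipeline — counts summed over a category's sentences,
decreasing order, alphabetical ties — is exercised without any terminology
licensing. The packaged ~180-entry breast-cancer lexicon covers treatments,
symptoms, emotions, resources and daily-living terms; plain counts order
the output.

## Gap assessment

* **Duplicate rule.** A need sentence is dropped if it is labelled
  `previous` and immediately follows another need sentence in the same
  post (a restatement like "Any answers out there?").
* **Referential resolution.** A retained `previous` sentence takes its
  query terms *only* from the nearest sentence with a non-social
  information category. "Nearest" is measured in sentences (not posts),
  with ties to the preceding side; a conversation with no such antecedent
  falls back to the sentence itself with a warning.
* **Query terms.** Stop-words (packaged ~190-word list including forum
  artifacts like "hi", "thanks") are removed; terms are scored tf · idf
  with raw counts and the smoothed idf ln((N+1)/(df+1)) + 1; the top ten
  survive, ties alphabetical. The idf collection is the education-page
  index by default — terms are weighted by rarity in the *target*
  collection — with corpus-based idf available as a switch.
* **Retrieval.** Okapi BM25 with k1 = 1.2, b = 0.75 and
  idf = ln(1 + (N − df + 0.5)/(df + 0.5)), the default behaviour of the
  search engine commonly used for this task; whole pages are the indexed
  unit so a gap is not overestimated when query terms span sections. Two
  pages are returned per query (configurable upward); ties break by page
  id. Distinct query terms contribute once each — the tf-idf weights select
  terms but do not enter the BM25 score. No synonym expansion is performed,
  which can overestimate gaps when materials use different terminology.
* **Statistics.** Percent agreement is the unadjusted fraction of rated
  documents with identical verdicts (mean over pairs, flagged, when more
  than two raters). Coverage-any / coverage-all are fractions of queries
  with at least one retrieved document judged relevant by ≥ 1 / by all
  raters; the complements bracket the knowledge gap.

## Validation strategy and problem sizes

The test suite works at three levels. Worked examples reproduce published
summary arithmetic exactly (percent agreement 86.8% from 15 + 221 agreed
verdicts of 272; coverage 33.1% / 12.5% from 45 and 17 of 136 queries;
F = .63 from P = .62, R = .65; prevalence 5.7% from 110 of 1943). Unit
oracles check each operation against brute force or hand computation (BM25
against an independent formula evaluation; rule induction against
exhaustive subset search). Property suites run the pipeline end to end on
generated data: a seeded MC-profile corpus of 1943 sentences reproduces the
mean sentence length within ±0.5 words; with perfect raters, measured
all-rater coverage tracks the education generator's coverage fraction
within ±0.1 across the whole dial; and adding local-context features
increases macro-F on label-autocorrelated corpora (one-sided paired test
over ten seeds). The coverage-recovery and ablation suites use a
*topic-balanced* generator configuration (uniform category mixture) rather
than the skewed study mixture, because the recovery identity
"expected coverage = coverage fraction" only holds when query topics are
exchangeable; under the study mixture a single run's coverage depends
heavily on whether the dominant medical topic falls in the covered set.
Test corpora range from hand-built 3-sentence fixtures to ~5000 generated
sentences (for distributional convergence); classifier suites use 8–40
conversation corpora and 5-fold splits, sizes at which every check runs in
seconds while still exercising stratification and leakage control.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 7, n_conversations = 40,
                       coverage_fraction = 0.5)
run_pipeline(cfg)
```

This writes the corpus (JSONL), annotations, descriptive statistics,
induced ruleset with a held-out evaluation, the rules-vs-statistical need
classifier comparison, the concept profile, queries, retrieval results,
simulated verdicts, the gap report, a markdown review file for human
raters, a timestamped log, and a manifest with the MD5 checksum of every
artifact; re-running the same config reproduces identical checksums.

## Known limitations

Synthetic validation bounds correctness, not real-world accuracy (see
above). The rule-based screener inherits the known failure modes of bigram
patterns — unseen phrasings and adverbial uses of cue bigrams such as "how
long" — and spelling correction is deliberately out of scope. Sequential
decoding is greedy (no lookahead and no sequence model), the documented
production trade-off. MetaMap-style concept normalisation, UMLS
integration, query synonym expansion and live-forum scraping are out of
scope by design.
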