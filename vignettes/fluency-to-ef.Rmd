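---
title: "Predicting executive function from comprehensive verbal-fluency features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting executive function from comprehensive verbal-fluency features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencyEF)
library(dplyr)
```

## The problem

Semantic verbal fluency (sVF) tasks — "name as many animals as you can in
two minutes" — are among the cheapest and most widely administered
neuropsychological instruments. Clinically they are almost always scored
by a single number, the count of correctly produced words, yet a recorded
fluency session carries far more information: what kinds of errors were
made, how speech pauses evolve over the task, and how semantically related
successive words are. `fluencyEF` implements a complete analysis chain
that extracts a comprehensive 43-feature profile from coded, time-stamped
fluency transcripts and asks, with a cross-validated machine-learning
procedure, how well each variable of a large executive-function (EF) test
battery can be predicted from that profile — and how much is lost when
only the classical sum scores are used.

The package covers three tasks: two simple category tasks (t1 = animals,
t2 = jobs) and a switching task (t3) alternating between sports and
fruits, each lasting 120 s.

## Data model

Sessions are tidy tables, one row per produced token, with columns
`participant_id`, `task`, `word`, `onset`, `offset`, `code`
(`correct`, `repetition_error`, `category_error`) and, for the switching
task, a `category` label. `read_sessions()` reads the TSV transcript
dialect, `read_textgrid()` converts a Praat TextGrid interval tier
(coding is edited downstream), and `validate_sessions()` enforces the
invariants: sorted, non-overlapping token intervals inside the task
duration, category labels on every switching-task token, and
category-error codes confined to the switching task. The task clock
starts at the end of the instruction (t = 0); the first token may begin
later, and the stretch before the first word is not counted as a latency.

EF scores are a wide table of 68 variables distributed over 14 tests in
five domains (cognitive flexibility, working memory, inhibition,
attention, vigilance). The exact variable inventory of a given study is
an editable registry (`ef_schema()`); the bundled default distributes 68
documented, package-invented variable names over the 14 tests with a
`polarity` (whether larger is better) and a `kind` tag separating
substantive variables from reaction-time variables.

## The 43 features

`build_feature_table()` produces exactly 43 features per participant:

* **Sum scores (5)** — correct words per task, their total, and the
  switch coefficient `sum_t3 / ((sum_t1 + sum_t2) / 2)` relating
  switching-task to simple-task output (undefined when the denominator
  is zero). Sums count *only* correct-coded tokens.
* **Error counts (4)** — repetition errors per task and category errors
  in the switching task. Repetition errors in the switching task are
  included: the downstream analyses use that feature, and it is the only
  reading under which the full set has 43 members.
* **Latencies (18)** — a latency is the pause from one token's offset to
  the next token's onset, computed over *all* tokens regardless of code,
  because errors occupy speaking time. Each task is split into four
  30-second intervals i1–i4; a pause belongs to the interval containing
  its start. Per task: overall mean, the four interval means, and the
  slowing index i4 − i1 (either sign; undefined when i1 or i4 has no
  pause).
* **Semantic relatedness (16)** — per task, the *sequential* mean over
  consecutive correct-word pairs in production order and the *cumulative*
  mean over all unordered correct-word pairs, plus per-category
  sequential means in the switching task (consecutive-in-production
  pairs sharing a category label; under strict alternation no such pair
  exists and the feature is missing). The eight aggregates are computed
  twice, once on each semantic backend (`_tax`, `_emb`).

Word pairs with undefined similarity — a word missing from the lexical
resource, or synsets in different graph components — are deleted before
averaging, and the two neighbours of a deleted word are *not* spliced
into a new consecutive pair: the pair is deleted, not the word. Error
tokens are excluded from semantic means (content features) but included
in latency computation (time features); both filters are deliberate and
documented here rather than configurable switches hidden in calls.

## Semantic backends

Two interchangeable relatedness measures are implemented:

* **Taxonomy shortest path.** On an undirected, unweighted graph of
  synsets connected by semantic relations,
  `sim(s1, s2) = (MAXSHORTESTPATH − length(s1, s2)) / MAXSHORTESTPATH`,
  where `length` is the hop count of the shortest path and
  `MAXSHORTESTPATH` the longest *finite* shortest path in the taxonomy.
  Identical synsets score 1; a diameter-realizing pair scores 0. Words
  with several senses are resolved by choosing the sense pair with the
  closest relatedness (the maximum similarity). Cross-component pairs
  are undefined, mirroring the missing-entry deletion rule, because the
  formula is meaningless at infinite length.
* **Embedding cosine.** Word vectors in word2vec text format; cosine
  similarity, undefined for missing words. Cosine can be negative for
  arbitrary vectors; values enter the means unclipped since only the
  relative ordering matters downstream.

The package ships a small synthetic two-level toy taxonomy (four task
categories split into domain subtrees, 159 synsets, 137 words, including
the deliberately ambiguous "kiwi") with matched 16-dimensional vectors.
It is a test and demo resource, not a stand-in for a real
lexical-semantic net; studies plug in their own resource files.

## Prediction engine

`run_repeated_cv()` scores one EF target; `predict_battery()` maps it
over all 68. The protocol, per target:

1. Ten-fold cross-validation, repeated ten times with fresh random
   partitions — 100 prediction models per target.
2. Within each fold, using training rows only: missing features are
   imputed with training-fold medians (forests need complete inputs and
   the median is fold-safe), features are z-scored, and sex, age and
   education are regressed out by ordinary least squares; the training
   coefficients are then applied to the held-out fold. Nothing derived
   from test rows ever enters a fitted parameter — the suite asserts
   this by a mutation test.
3. A 100-tree random-forest regressor (via `ranger`, single-threaded,
   seeded; all other hyperparameters at the implementation's regression
   defaults, recorded in the run manifest) is fitted on the training
   fold and predicts the held-out fold; the Pearson correlation between
   true and predicted scores is recorded.
4. Prediction performance is the mean fold correlation over the 100
   models. The p value treats that mean as a correlation observed at
   n = participants, `t = r√(n−2)/√(1−r²)`, two-sided. A permutation
   alternative (re-running the whole procedure on permuted targets) is
   available via `cv_config(p_method = "permutation")`; the parametric
   test is the default because simulation shows it is close to nominal
   here (see "Calibration" below). Targets with p < 0.01 are flagged
   *highly predictable*.

Targets are left on their raw scale by default (Pearson correlation is
scale-invariant); `standardize_target = TRUE` restores strict
z-scoring of both sides. Fold partitions depend only on the seed and the
number of scored participants, so the full and classical arms of a
comparison (same seed) use identical folds, and identical seeds
reproduce every number exactly.

Feature importance is out-of-bag permutation importance averaged over
the 100 models, with ties broken by canonical feature order;
`followup_spearman()` reports rank correlations of the top-5 features
with the raw (non-residualized) target, flagged at p < 0.05
(significant) and p < 0.1 (trend), matching the reporting convention of
the tables this layout mirrors. `compare_feature_sets()` contrasts the
full 43-feature arm with the classical 4-sum-score arm per target and
per domain.

## Synthetic cohort generator

Because no participant-level study data are distributable, the package
includes a first-class generator (`generate_cohort()`) that emulates the
statistical structure the analysis assumes, with a default size of 230
participants aged 20–55 (mean 35.2, sd 11.1, 40% male, education
distributed 8/63/69/90 across four ordinal levels).

Five latent abilities (flexibility, working memory, inhibition,
attention, speed; correlated 0.3 in the realistic scenario) drive both
sides:

* **Word production** is a cluster-structured walk over the toy
  taxonomy's subtrees: stay in the current subtree with a continuation
  probability that rises with working memory, otherwise jump; sampling
  is without replacement so an exhausted subtree forces a switch (which
  keeps repetition errors a deliberate injection, never an artifact).
* **Latencies** are lognormal with a mean that falls with the speed
  ability (and rises with age in the realistic scenario), a time-on-task
  slowing slope flattened by flexibility, and a cluster-switch penalty.
* **Errors**: a repetition hazard (falling with inhibition and working
  memory) re-emits an earlier word coded `repetition_error`; a
  category hazard in the switching task emits a word from a non-task
  category coded `category_error`. Dual-sense words that also belong to
  a task category are never used as category errors.
* **Switching behaviour**: alternation compliance rises with
  flexibility. A compliance lapse produces a same-category word that is
  *coded correct* — a behavioural lapse rather than a scored error.
  This choice keeps the per-category sequential features defined for
  most participants (under error-coded lapses and strict alternation
  they would be structurally missing) and reflects the lenient end of
  real coding conventions.
* **EF scores** are noisy linear combinations of the abilities: each
  variable loads on its domain ability plus the speed ability, with
  reaction-time variables dominated by speed — mirroring the observation
  that many predictable battery variables mainly reflect general
  processing speed. Scores are shifted/scaled and sign-flipped per the
  registry's polarity.

Three scenarios fix the coupling structure. `realistic` switches
everything on, including negative age slopes on the abilities (so raw
sum scores correlate negatively with age and the correlation attenuates
after residualization). `null` zeroes *all* loadings, hazard couplings,
production couplings and confound effects: EF scores are pure noise and
no feature–target association exists by construction. `planted` routes
signal exclusively through semantic cohesion (working memory →
continuation probability) and latency slope (flexibility → slowing
tilt) into one designated target, while word counts are driven by the
independent speed ability alone — the planted target is predictable from
the comprehensive features but invisible to sum scores, turning the
full-versus-classical superiority claim into a testable property.
`describe_truth()` returns the exact planted couplings for recovery
tests.

What the generator does *not* emulate: German morphology and word
frequency, acoustic or articulatory realism, filled pauses,
perseverative chains, practice effects, or the empirical covariance of
a real EF battery. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind assumed*, not that real data
contain that structure.

## Calibration and numerical choices

* Degenerate inputs: constant targets are skipped with a report entry;
  targets with fewer than 20 scored participants are refused;
  zero-variance features pass through preprocessing as all-zeros with a
  single warning per run.
* An undefined mean (no surviving pair, empty interval) is `NA`, never
  0 — missingness is information and is imputed only inside folds.
* Ties in importance rankings are broken by the canonical feature order
  so reports are reproducible.
* Sub-seeds for folds and forests are derived from the master seed by a
  fixed integer recurrence, keeping every value inside the 32-bit
  range.

The test suite includes a null-calibration study: under the null
generator the fraction of targets flagged at p < 0.01 must stay inside
the binomial 99% envelope, and the grand mean of the mean correlations
must sit within ±0.03 of zero. The suite runs this at a reduced but
fixed footprint chosen once — cohorts of n = 120, five replicate
batteries at the full engine scale (tenfold × 10 repetitions, 100
trees) for the envelope, and fifteen further seeds at a lighter scale
(first 10 targets, 2 repetitions, 50 trees) for the centring statistic;
signal-recovery checks use ten cohorts of n = 230. Exploratory
simulation during development showed the parametric screen is close to
nominal (if anything slightly conservative) at both scales.

## Limitations

* The toy taxonomy's shallow tree yields coarse similarity values
  (multiples of 1/6); real lexical nets give a finer gradation.
* The parametric p value treats the mean fold correlation as a single
  correlation; its calibration was verified by simulation for the
  configurations shipped here, not proven in general — the permutation
  option exists for studies that need exactness.
* The comparison of feature sets shares folds between arms but not a
  formal paired test; the reported quantity is the per-target
  difference in mean correlation and the significance counts.
* Automatic error coding from raw text, audio processing and forced
  alignment are out of scope: transcripts arrive coded and
  time-stamped.
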