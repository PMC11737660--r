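---
title: "How the assessment machine works: models, scoring, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How the assessment machine works: models, scoring, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitr)
```

`sitr` implements a codebook-based machine that assesses free-text
self-injury narratives: it predicts which of four clinical training
subsets a writing most resembles, retrieves severity and
treatment-outcome estimates from counselor judgments made on that subset,
and retrieves intervention priorities from the single most similar
training case. This vignette explains the model and every place where the
design was genuinely open, so a reader can judge what the package's tests
do and do not establish.

## Training data model

A training case is a document plus paired counselor judgments: severity,
expected intervention difficulty, and expected (negative) treatment
outcome, each on a 1–7 Likert scale, plus a ranking of five intervention
domains. Severity and difficulty measure nearly the same construct in
such panels, so `merge_judgments()` pools them into one merged severity
(the mean of all severity and difficulty values across raters). An open
question was whether to average within rater first; for equal rater
counts the two orders coincide, and we pool directly, which also handles
unbalanced panels gracefully.

`partition_subsets()` crosses merged severity against mean outcome at
thresholds (default 4.0 and 3.5, both inclusive) to produce subsets A–D.
The thresholds are configuration, not constants: the defaults are the
midpoint-style pair consistent with all four published subset summary
rows (severity means 4.44/4.53 above, 3.30/3.58 below 4.0; outcome means
3.94/3.65 above, 2.88/2.55 below 3.5).

## Tokenization

The reference pipeline for Korean text uses an external morphological
analyzer. The built-in default (`tokenize()`) must work without it: NFC
normalization, lowercasing (caseless scripts pass through), and maximal
runs of Unicode word characters. Any function `text -> tokens` can be
plugged in as an adapter, so a KOMORAN-style analyzer slot is a one-line
configuration, and the default stoplist
(`inst/extdata/stoplist_default.txt`) is fully replaceable — which
morphemes are "empty" is language-specific.

## Topic models

Each subset gets its own LDA model, fit by collapsed Gibbs sampling
(`fit_lda()`, Rcpp). Defaults: K = 10 topics per subset, alpha = 0.1,
beta = 0.01, 1000 sweeps with 500 burn-in. The reference work reports
none of these, so we chose standard sparse-topic defaults and exposed all
of them. Two numerical choices matter downstream:

* **Point estimation from the final count state**, not posterior
  averaging. Averaging mixes topic labels across sweeps and destabilizes
  the codebook's topic assignment; the final state is deterministic for a
  fixed seed and keeps the audit trail stable. Averaging is available via
  `average = TRUE`.
* **Proportion estimates are rounded half-up** (`floor(x + 0.5)`) to
  integer percents, so printed codebooks are identical across platforms
  regardless of the C library's rounding mode.

`topic_coherence()` implements the UMass document co-occurrence score as
a model-selection diagnostic only; nothing downstream consumes it.

## The codebook

`build_codebook()` extracts each topic's top tokens (default 20 per
topic, minimum weight 0.001 — the printed reference codebook clearly
holds more than the three example tokens per topic it displays, and
bounding the list keeps scores stable). A token appearing in several
topics of one subset is housed in the topic where its weight is maximal
(lowest index on exact ties) so that every profile entry traces to
exactly one topic.

Representativeness scores standardize raw within-subset frequencies; the
reference description says only "standardized … based on their
frequency". We chose **within-subset min–max to [0, 1]**: it keeps
additive scoring non-negative, makes the +1 bonuses commensurate with
doubling the strongest token, and has an unambiguous degenerate case (all
frequencies equal → all scores 1, so matches still count).

## H1: subset scoring and selection

`match_tokens()` scans the filtered input in text order. Scoring rules,
each a deliberate design decision:

* **Distinct-type scoring** — each token type counts once per subset, at
  its first occurrence. Repetition and sheer length otherwise dominate
  the score; the reference text never says whether repeats accumulate.
* **Position bonus** — the first three distinct matched token types
  receive `w_pos` (default 1), once per token, credited in the first
  subset (screening order A, B, C, D) where the token matches. The
  worked-example arithmetic (scores 3.3 vs 3.5 for the `pain / knife /
  alone` fixture) is only reproducible under this once-per-token reading;
  the bonus magnitude, like the risk bonus, is configuration because
  whether the original "+1" lived on the standardized or raw-frequency
  scale is unknowable.
* **Risk bonus** — risk-lexicon tokens add `w_risk` in every subset where
  they match; a dangerous token is dangerous wherever it appears.

`h1_select_subset()` ranks by probability score, then by the number of
matched tokens, then by the fixed precedence **B ≻ A ≻ D ≻ C**. The two
ranking parameters are described as used "simultaneously" without a
combination rule; we rank lexicographically, and break exact ties
severity-conservatively (a screening tool should over- rather than
under-triage).

`assess()` refuses inputs with fewer than `min_matches = 3` distinct
codebook matches (condition class `sitr_insufficient_evidence`). The
reference workflow dropped 3 of 50 survey writings as too short to infer
from but states no threshold; three matches is the smallest count for
which the position-bonus logic is even fully exercised.

Severity and outcome estimates are the **selected subset's stored
judgment means** — H1's job is to retrieve the Likert-type judgments made
for the subset; the matched case contributes only the ranking-type
priorities. This division of labor is kept strict.

## H2: case matching

The input's topic profile maps each topic title of the selected subset to
the topic's proportion estimate if any input token matches an entry of
that topic, else 0. Profiles are compared by **cosine similarity**
(scale-free over proportion-valued vectors; the reference says only
"compared"). Ties prefer the case sharing more nonzero topics, then the
lexicographically smallest case id; an all-zero input profile has
similarity 0 to everything and falls through to the tie rules. All three
rules are exercised exhaustively in the tests.

## Synthetic corpus generator

`generator_spec()` / `sample_corpus()` stand in for the unpublished
corpus. Per subset: a vocabulary of V = 400 abstract pseudo-word types
split into K = 10 disjoint per-topic slices with Zipf-shaped weights;
document mixtures ~ Dirichlet(0.3); document lengths lognormal with
moments matched to 103.85 ± 61.38 tokens (positive and right-skewed, as
token counts are), clamped at ≥ 5. Subset sizes default to 26/62/64/26.
The overlap fraction ω replaces a fraction of every topic slice with
tokens from a pool shared across subsets and is the single difficulty
knob: ω = 0 makes subsets vocabulary-disjoint (recovery should be
perfect), ω = 1 makes them indistinguishable.

Judgment truth is drawn from subset-conditional normals matching the
published summary means/SDs, truncated (margin 0.25) to the subset's
severity/outcome region so that the simulated raters' merged values stay
consistent with the generating label — without truncation a draw near a
threshold could legitimately flip subsets, which would break the
label-consistency invariant every downstream test relies on. The cost is
that empirical subset means sit slightly further from the thresholds than
the nominal means; tests therefore compare against the truncated-truth
expectation rather than the nominal value. Rater noise is Gaussian on the
true score, rounded and clamped to 1–7; `calibrate_rater_noise()` finds
the noise SD whose paired-rater kappa matches a target (≈ 1.0 for the
"fair" 0.40 regime). An optional per-rater bias term is not modeled: the
true noise structure of the original panels is unreported, and pure noise
is the weaker assumption.

What the generator does **not** emulate: real lexical semantics, topic
correlations across subsets, document-length/severity dependence, and
rater biases that correlate with content. Perfect recovery at ω = 0
therefore shows the pipeline is correct, not that real Korean posts are
this separable; the ω-sweep (accuracy decreasing toward chance as
vocabularies merge) is the meaningful robustness check.

## Psychometric statistics

Cohen's kappa (unweighted by default — the reference reports plain kappa
on Likert judgments; linear/quadratic weights available) with
Landis–Koch bands; Shrout–Fleiss ICC(2,k) (two-way random effects,
absolute agreement, average measures) from the two-way ANOVA mean
squares; Pearson correlation; one-way MANOVA using Wilks' Λ with Rao's F
approximation (no statistic is named in the reference; Wilks is the SPSS
default) plus univariate follow-ups and pairwise mean differences with
pooled-variance CIs; hierarchical regression with ΔR² and
F-change = (ΔR²/q) / ((1 − R²)/(n − p − 1)); Shapiro–Wilk and
median-centered Levene assumption checks. Every statistic is tested
against an independent brute-force oracle on ≥ 1000 random instances at
1e-8. One caveat worth knowing: the ICC(2,k) formula's denominator can go
negative on data with no target variance, in which case the ratio is not
a reliability; the ≤ 1 bound is asserted on rating-shaped data.

`run_validation()` reproduces the beta-test workflow: assess held-out
cases (logging insufficient-evidence exclusions), compare machine vs
reference severity/outcome with a one-way MANOVA, and pass when the
multivariate test is non-significant at α = 0.05. Non-significance is a
weak notion of equivalence — absence of evidence, not evidence of
absence — so the criterion is configurable and the caveat is part of the
API documentation.

## Problem sizes used by the test suite

The test suite fits the full study-condition pipeline (160 training
cases, V = 400, K = 10, 1000 sweeps) once, runs the ω-sweep
(ω ∈ {0, 0.25, 0.5, 0.75} × 10 seeds) at 500 sweeps, and uses a small
cached pipeline (48 cases, K = 5, 400 sweeps) for the report and
validation tests; statistical oracles run at n between 4 and 40 per
instance. These sizes were chosen so the whole suite gives tight Monte
Carlo evidence in a few minutes on one CPU; all of them scale up by
changing the spec objects only.

## Known limitations

* Severity/outcome estimates are subset means: the machine cannot produce
  estimates outside the four stored pairs, by construction.
* The codebook is static; recovery-oriented topics and longitudinal
  change across repeated writings by the same person are out of scope.
* Reports are a screening aid; the caveat block is always rendered and
  reports never contain raw training-case text, only case identifiers.
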