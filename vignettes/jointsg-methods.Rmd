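---
title: "Joint code-word embeddings: model, training and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint code-word embeddings: model, training and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(jointsg)
```

## The problem and the model

A hospital visit couples an unordered set of ICD-9 diagnosis codes
*D* with the ordered word sequence *N* of its clinical notes. The two
describe the same clinical reality in different languages, and many
tasks — text-based phenotyping, code assignment, comorbidity
exploration — reduce to asking how similar a *code* is to a *word*.
`jointsg` answers this by training one skip-gram negative-sampling
(SGNS) model over both token families, with contexts chosen to
respect their structure:

* codes are set-like: a code target's context is every other co-visit
  code and every note word occurrence;
* words are sequence-like: a word target's context is a ±*q* window of
  neighbouring words (which preserves syntactic regularities) plus
  every co-visit code.

Each positive (target, context) pair contributes
log σ(V_t·U_c), and K negatives n drawn from the context namespace's
noise distribution contribute log(1 − σ(V_t·U_n)). Stochastic
gradient ascent updates one pair at a time; both matrices V
(input/target) and U (context) span the full vocabulary
(|W|+|C|) × T. All similarity queries and visit features use V only;
U is persisted so training can be resumed, but it is never queried.

Two restrictions of the trainer, `words_only` and `codes_only`,
recover plain SGNS within one namespace; with empty code sets the
joint pair stream is provably identical to a window-scan skip-gram
stream, and the test suite asserts that equality exactly.

## Preprocessing

Notes are lowercased and split on any non-alphanumeric character;
tokens containing a digit are dropped, then stopwords (a bundled
Snowball English list by default — the choice is configurable because
no canonical clinical stopword list exists). An optional dictionary
word list reproduces the stricter standard-vocabulary regime in which
misspellings and nonstandard terms are excluded; leaving it off keeps
clinically meaningful nonstandard tokens (drug names, abbreviations),
which is the regime that surfaces treatment vocabulary.

ICD-9 codes are grouped by their first three characters after
removing dots and whitespace ("2901" → "290"), because many full-depth
codes are too rare to learn from; V- and E-codes follow the same
uniform rule (e.g. "E8790" → "E87") — the alternative of treating them
specially has no obvious benefit and would complicate the contract.
Grouped codes carry an internal `ICD9:` prefix so no code string can
collide with a word; the prefix is stripped in all user-facing output.
Words occurring fewer than 50 times and codes occurring fewer than 5
times in the corpus are removed (inclusive-keep thresholds; both
configurable). Vocabulary ids are assigned words-first by descending
count with lexicographic tie-break, making indexing a pure function of
corpus and configuration.

A visit may contain several notes. They are concatenated with a
boundary sentinel, and word windows never cross a sentinel: windows
spanning two unrelated notes would manufacture co-occurrences that the
text does not contain. Code contexts, by contrast, deliberately span
the whole visit.

## Training parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `dim` (T) | 200 | vector dimensionality; standard for vocabularies of 10³–10⁵ tokens |
| `epochs` | 40 | passes over the corpus; empirically enough for convergence at corpus scale (validation runs use 30) |
| `window` (q) | 5 | word-context half-width |
| `negatives` (K) | 5 | negative samples per positive pair |
| `initial_lr` | 0.025 | SGD step; decays linearly to 1/100 of itself over all scheduled updates (the word2vec convention; a constant schedule is available) |
| `noise_power` | 0.75 | exponent on marginal counts for negative sampling; 0.75 is the SGNS convention that lifts rare tokens — set 1.0 for the literal marginal distribution |
| `pretrain_fraction` | 0.10 | share of visits used to pretrain word vectors words-only before joint training |
| `pretrain_epochs` | 5 | length of that phase; the phase is short because it only needs to give word vectors a head start, not converge them |

Initialization follows word2vec: V rows uniform in [−0.5/T, +0.5/T],
U at zero, from a seeded generator. Frequent-word subsampling is
deliberately omitted (no flag is silently applied to the user's
corpus). Word targets predict every co-visit code once per scanned
word, so long notes weight code-word pairs proportionally to their
length; that is the objective as defined, and it is implemented
faithfully.

Negative draws never leave the context's namespace: negatives for a
word context are words, for a code context codes. A drawn negative may
coincide with the target or context token; the gradient step evaluates
every sigmoid at the current point and then moves all rows at once, so
such collisions are handled exactly (the finite-difference tests cover
them explicitly).

## Determinism and numerics

All randomness — initialization, per-epoch visit shuffling, negative
sampling — runs through a self-contained xorshift128+ generator keyed
by the integer seed, independent of R's RNG state; identical
configurations give byte-identical models. The per-epoch shuffle is
published as `visit_schedule()`, which makes the exact pair stream of
any run auditable (`emit_training_pairs()`).

σ(x) is computed in the branchless-stable form (exp of a non-positive
argument only), and log σ(x) as −log1p(e^{−x}) / x − log1p(e^x), so
the objective is finite for |V_t·U_c| well beyond 10⁴. A non-finite
dot product aborts training with the offending token id rather than
silently corrupting the model. Ranking ties in queries and in top-k
prediction break lexicographically on the token string and by
ascending code id respectively, so results are reproducible across
platforms. Degenerate inputs follow explicit contracts: visits with
empty code sets still train their words (and vice versa), visits empty
on both sides are dropped, and averaging feature schemes map an empty
token set to a zero block rather than failing.

## Next-visit evaluation

Consecutive visits of each patient (sorted by admission time, visit-id
tie-break with a warning) form (features of visit *t*, codes of visit
*t*+1) examples; single-visit patients contribute nothing. The softmax
predictor Z is trained by per-example SGD on categorical cross-entropy
for 100 epochs. Because an example carries several true codes and the
target encoding is not otherwise fixed, the target distribution is
uniform over the true code set — the least-informative choice
consistent with multi-label cross-entropy. The optimizer is plain SGD
with a constant rate (default 0.5) and no regularization; the task
exists to compare feature schemes, not to maximize absolute recall, so
the simplest optimizer keeps the comparison clean. Top-k recall is
macro-averaged over examples and reported with the standard error of
the mean, computed per example so that the ± reflects between-example
variance. The harness also scores externally computed feature matrices
(TSV), so decomposition baselines produced elsewhere can be compared
under identical splits and training.

## What the synthetic generator does and does not show

Real credentialed EHR corpora cannot ship with a package, so the
generator builds cohorts whose ground truth is known: each of
`n_topics` latent topics owns disjoint pools of codes and words; a
patient's first visit topic is uniform and later visits keep the topic
with probability 0.8 (else redraw), giving the next-visit task
learnable signal; each visit draws 3 codes from its topic and a
40-word note in which 20% of words come from a shared topic-free noise
pool. Defaults — 500 patients, 1–4 visits each, 5 topics, 8 codes and
40 words per topic — are the package's validation conditions: large
enough that every topic word clears the standard frequency threshold
of 50, small enough that the full pipeline (30 epochs of joint
training at T = 200 plus the prediction benchmark) runs in about a
minute on one core. Synthetic codes are 3-character strings so
grouping is the identity; a `long_codes` flag emits 4–5 character
codes to exercise grouping end to end.

Validation on these cohorts shows that the implementation recovers
planted structure: macro retrieval precision at 15 words reaches 1.0,
the within-topic code-word cosine exceeds the cross-topic mean by
about 0.6, and concatenated-average features lift top-20-of-40 recall
far above the 0.5 chance rate. What it does **not** show: anything
about real clinical language — the generator mimics neither note
length distributions, nor ICD-9's long-tailed frequencies, nor
polysemy, negation, or section structure in notes. Passing these tests
certifies the machinery, not clinical performance; absolute numbers on
real corpora will differ.

## Known limitations

* Tokens below the frequency thresholds are discarded entirely; no
  subword or hierarchy information rescues rare codes or words.
* Averaged word vectors are a crude visit representation for long
  notes; sequence models would use the notes better.
* The reference trainer is single-threaded (determinism is part of its
  contract); there is no asynchronous multi-core path.
* Vocabularies are assumed small enough for exact brute-force
  neighbour search; no approximate index is provided.
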