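---
title: "Methods: SMS content analysis and engagement modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMS content analysis and engagement modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsengage)
```

## The problem

SMS-based chronic-disease support programs send scheduled text messages to
participants and, in some programs, invite replies. Two questions recur when
such programs are evaluated: can the *functional intent* of outgoing
messages (informative, instructional, motivational, supportive,
notification) and the *category* of participant replies (stop, thanks,
question, reporting healthy, reporting struggle, general comment, other) be
classified automatically; and is message intent associated with
participants prematurely stopping the program or with their engagement?

`smsengage` implements that full analysis pipeline for communication logs —
outgoing messages, replies linked to the message they answer, and a
participant roster with withdrawal status — together with a synthetic log
generator with known ground truth, because real program logs typically
cannot be shared.

## Near-duplicate clustering

Program messages are template-derived: the same message is personalised and
re-sent to many participants. Treating those near-copies as independent
records would let a classifier memorise templates rather than learn
intents, and would leak information across cross-validation folds.

Messages are therefore grouped by similarity first. Texts are lowercased
and tokenized into word tokens, standalone punctuation tokens (punctuation
counts as a token here), and bracketed placeholder slots such as
`[person_name]` kept whole. Tokens are stemmed with the Lancaster
(Paice/Husk) algorithm using the published default rule table, and each
text becomes the *set* of its distinct stems. Similarity between two texts
is the Jaccard index of their stem sets, and any pair with similarity
*strictly above* 0.5 is joined; clusters are the connected components of
that graph. Transitive closure is the only reading under which "any two
sufficiently similar texts share a cluster" is self-consistent, and it
makes the output a partition that is invariant to input order (clusters are
relabelled `0..C-1` by smallest member position).

Conventions worth stating: ties at exactly the threshold do not merge; two
empty token sets have similarity 1 (identical content) while empty versus
non-empty is 0. The pairwise computation is exact (no locality hashing) —
corpora of a few thousand messages are well within reach of the sparse
token-incidence crossproduct used internally.

One property of the reference Lancaster rule table deserves a note: it is
not idempotent. Rules flagged *intact-only* fire only on unmodified words,
so re-feeding a stem as a fresh word can strip further (`another` →
`anoth` → `ano`). The implementation is faithful to the published table;
stems are computed exactly once per token.

## Feature encoding

The default text encoder is a deterministic hashed n-gram vectorizer:
stemmed token unigrams and bigrams are bucketed by a signed 32-bit FNV-1a
hash into `dim` buckets (default 768), counts are log-scaled
(`sign(c)·log(1+|c|)`), and each vector is L2-normalised so one
regularisation scale suits all texts. Signed hashing (a second hash decides
±1) cancels collision bias in expectation. The encoder is a pure function
of the text and the configuration — identical across runs and platforms —
and never produces non-finite values.

A pretrained sentence-embedding backend can be plugged in through
`encoder_config(encoder = "pretrained_embedding", provider = ...)`; the
provider must honour the same contract (fixed width, deterministic,
finite). No provider is bundled, and requesting one without supplying it is
an explicit capability error — never a silent fallback. Pooling strategy is
the provider's business and should be recorded by the caller.

Reply classification is contextual: reply features are the text encoding
concatenated with the one-hot intent of the eliciting message
(`dim + 5` columns, canonical intent order).

## Classification and leakage-controlled evaluation

The classifier is an L2-regularised multinomial logistic model: it
maximises the multinomial log-likelihood minus `1/(2C)`‖W‖², intercepts
unpenalised, fitted by L-BFGS with analytic gradients from a zero start
(the penalised objective is strictly convex in the weights, so the optimum
is unique and the fit deterministic; convergence is checked on the gradient
norm and flagged, never silently ignored). Predictions are the probability
argmax with ties broken toward the earlier class in canonical order.

Evaluation uses nested cross-validation with *group-constrained* folds:
records sharing a group id — the Jaccard cluster for messages, the
participant for replies — are never split across train and test, at the
outer level (performance estimation) and the inner level (hyperparameter
selection) alike. Folds are built greedily: groups sorted by descending
size, each assigned to the currently smallest fold; this balances fold
sizes, is deterministic, and requires at least `k` distinct groups. The
inner 10-fold grid search selects `C` from {0.01, 0.1, 1, 10, 100} — a
grid spanning under- to over-regularised regimes for unit-norm features —
by mean balanced accuracy, ties to the smallest `C` (preferring the
stronger prior). `leakage_violations()` re-audits every split
programmatically.

Metrics follow the one-vs-rest convention: per-class sensitivity,
specificity, PPV, NPV, FPR, FNR and F1 from the fold confusion matrix;
balanced accuracy is the unweighted mean of per-class sensitivities. Zero
denominators yield *undefined* (`NA`), and undefined cells are excluded
from macroaverages rather than coerced to 0, which would artificially
deflate rare-class summaries. At the fold level a class absent from the
fold's truth is likewise excluded from that fold's balanced accuracy.
Across folds each metric is reported as mean (SD), and balanced accuracy
additionally as a two-sided 95% Student-t interval over the outer folds —
a pragmatic choice among defensible aggregation schemes, and stated as
such. ROC curves are one-vs-rest over the pooled outer-fold probabilities,
with trapezoidal AUC; the trapezoid on a ROC step curve equals the
pairwise concordance probability with ties counted one half, and the test
suite asserts that identity to 1e-12.

## Outcomes and associations

A participant *stopped prematurely* if any reply is of category STOP or if
they withdrew; a participant is *engaged* if they replied at least 3 times
and did not stop. Zero-reply participants are included (not engaged).

Associations are estimated at the *reply level*: each analyzable reply is
one event, its exposure the intent of the eliciting message, its outcomes
(a) whether the reply itself is a STOP and (b) whether its sender is
engaged. The reply is the only unit under which a reply-type outcome is
well defined, but the choice deserves emphasis because replies from one
participant are not independent; no clustering correction is applied (the
models are plain univariate logistic regressions), so p-values should be
read accordingly. Control-arm replies are excluded by default since
intervention messages define the exposure; STOP replies themselves remain
in the engagement regressions (both choices configurable).

For each intent, a logistic model of the outcome on the intent indicator
gives β, OR = exp(β), a Wald 95% CI `exp(β ± 1.96·SE)` and a two-sided
Wald p — overall and within each program type — and a second model with a
program-type interaction term tests effect modification; in the saturated
binary×binary case the interaction coefficient equals the log ratio of the
stratum ORs exactly, an identity the tests exploit. Separation and
non-convergence raise diagnostic errors rather than returning numbers.
Chi-square tests of independence (Pearson, no continuity correction)
accompany the regressions.

## The synthetic generator

`generate_log()` emulates a two-program corpus: a 1-way program (replies
monitored but not encouraged, 180 days) and a 2-way program (replies
encouraged, 360 days), mirroring the 6- versus 12-month program designs
this kind of analysis targets. Per intervention participant it schedules
`messages_per_participant` messages with intents drawn from a per-program
simplex; texts are drawn from template banks in which every template of an
intent carries that intent's signature phrase while template-specific
content words keep within-intent templates below the 0.5 clustering
threshold — so clustering (within-template) and classification
(between-intent, generalising across clusters) are both non-trivial and
both solvable. Each token is perturbed with probability `paraphrase_noise`
(half filler-word swaps, half drops; default 0.1, at which two copies of a
template stay Jaccard-similar above 0.5 more than 95% of the time).

Replies are Bernoulli events with probability
`reply_propensity[intent] × L`, clamped to [0, 1], where `L` is a
per-participant lognormal multiplier (mean 1, log-scale SD 0.75) — the
engagement heterogeneity that makes a ≥3-replies threshold discriminating,
reflecting the empirical pattern that a small engaged subgroup contributes
most replies. Conditional on replying, a stop occurs with probability
`plogis(qlogis(p0) + log(OR[intent, program]))`, where `p0` is the STOP
entry of the reply-category simplex (default 0.05, consistent with the
few-percent stop rates such programs report) and `OR` the configured true
stop odds ratio; with a single exposed intent the reply-level
exposed-versus-rest odds ratio is exactly the configured value, which is
what the recovery suite estimates. Non-stop categories are drawn from the
intent's simplex renormalised without STOP. A stop ends the participant's
reply stream; withdrawals (default rate 0.03, roughly the withdrawn/lost
fractions seen in program rosters) suppress later replies and set the
roster flag. Infeasible configurations (a zero or unit baseline with a
non-unit OR) fail fast naming the offending cell.

Everything is driven by integer-seeded base-R RNG streams — no hash-order
dependence — so a seed reproduces a log byte for byte.
`with_text = FALSE` replaces text realisation with labelled placeholders
for Monte-Carlo suites that only consume the event structure; nothing
statistical changes.

What the generator does *not* emulate: real message wording beyond short
templates, free-text reply variability, seasonal or schedule effects,
program-specific reply-rate drift, or the real studies' odds ratios. Green
tests on synthetic corpora therefore certify the machinery — leakage-free
splitting, unbiased estimation, correct aggregation — not real-world
classifier accuracy.

## Problem sizes and numerical choices

The canned fixtures are deliberately small: `tiny` (~30 participants) for
smoke tests, `easy`/`hard` (52 participants, 360 messages) for full
nested-CV runs, `null_effect` (80 participants) for null-calibration
checks. The Monte-Carlo suites use 200 replicates of roughly 12,000 reply
events for odds-ratio recovery and coverage, and 400 replicates of 5,000
events for the size of the interaction test. Encoder width is 256 for the
fixture pipelines (the 768 default serves realistic corpora; on
360-message template corpora the narrower space loses nothing). Optimiser:
L-BFGS-B, `factr = 10`, up to 1000 iterations, convergence flagged on the
gradient norm. Tie-breaks are everywhere deterministic: smallest `C`,
earliest canonical class, smallest member position for cluster labels.

## Known limitations

- Within-participant correlation is ignored by design in the association
  models (plain logistic regression); robust or mixed-effects variants are
  out of scope.
- The hashed encoder cannot reproduce pretrained-embedding semantics;
  it is the offline-reproducible default, not a claim of equivalence.
- Printed per-class panels from cross-validated studies do not always
  average exactly to their printed summary cells (fold-weighting
  artifacts); `macroaverage()` implements the plain unweighted mean and
  the documentation flags, rather than reconciles, such cells.
- t-intervals over 10 outer folds are approximate; fold accuracies are
  not independent, so the intervals are indicative, not exact.
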