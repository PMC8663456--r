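# smsengage

Content analysis and engagement modelling for SMS-based health-support
programs.

Chronic-disease prevention programs delivered by SMS send scheduled,
template-derived text messages and — in two-way variants — invite
participant replies. `smsengage` is for researchers analysing the
communication logs of such programs. It answers two questions: can the
functional **intent** of outgoing messages (informative, instructional,
motivational, supportive, notification) and the **category** of replies
(stop, thanks, question, reporting healthy, reporting struggle, general
comment, other) be classified automatically; and is message intent
associated with **premature program stopping** (a stop reply or
withdrawal) or with **engagement** (at least 3 replies without stopping)?

## What it implements

- **Near-duplicate clustering.** Messages are tokenized (punctuation
  counts as tokens, `[person_name]`-style placeholders stay whole),
  stemmed with the Lancaster (Paice/Husk) rule table, and grouped by
  connected components of the graph joining pairs with stemmed-token
  Jaccard similarity > 0.5. Clusters double as anti-leakage groups.
- **Classification under leakage-controlled nested CV.** A deterministic
  hashed n-gram encoder (signed FNV-1a, log-scaled counts, L2-normalised;
  pretrained sentence embeddings pluggable) feeds an L2-regularised
  multinomial logistic model, `C` selected by inner 10-fold group-aware
  grid search maximising balanced accuracy, evaluated by outer 10-fold
  group-aware CV. Groups (message clusters; reply participants) never
  span train and test, and `leakage_violations()` audits every split.
- **Evaluation.** One-vs-rest sensitivity/specificity/PPV/NPV/FPR/FNR/F1
  per class as mean (SD) across folds, macroaverages (undefined cells
  excluded, never zero-filled), balanced accuracy
  `(1/K) Σ_k sens_k` with a Student-t 95% interval over outer folds, and
  one-vs-rest ROC curves with trapezoidal AUC (equal to pairwise
  concordance, ties half-counted).
- **Engagement analysis.** Per-participant stopped/engaged outcomes;
  reply-level logistic models `logit P(y) = α + β·x_intent` giving
  OR = exp(β) with Wald 95% CIs, per program stratum, plus program-type
  interaction models where β₃ equals the log ratio of stratum ORs in the
  saturated case; Pearson chi-square tests of independence.
- **Synthetic logs with known truth.** A seeded generator of two-program
  corpora (template texts with paraphrase noise, intent-conditional reply
  propensities and categories, configurable true stop odds ratios,
  lognormal engagement heterogeneity, withdrawals) so the whole pipeline
  is testable offline; `make_fixture("tiny"|"easy"|"hard"|"null_effect")`
  gives canned seeded corpora.

## Worked example

```r
library(smsengage)

fx <- make_fixture("easy")        # seeded synthetic corpus
fx$log
#> <communication_log> 360 messages, 142 replies, 52 participants

report <- run_pipeline(fx$log, pipeline_config(
  encoder = encoder_config(dim = 256),
  cv = cv_config(k_outer = 5, k_inner = 5)))
report
#> <run_report> 360 messages / 142 replies / 52 participants, 20 clusters
#>   intent model balanced accuracy: 1.000
#>   reply model balanced accuracy: 0.957
```

The 360 messages collapse into 20 clusters — one per generating template —
and with clusters held whole across folds the intent model still separates
the five intents perfectly (balanced accuracy 1.000: the easy fixture's
intents have disjoint core vocabularies by construction). The reply model,
grouped by participant, reaches 0.957. Association rows mirror the
outcome × intent × stratum layout:

```r
subset(report$associations, outcome == "STOP" & stratum == "ALL")
#>           intent    or ci_low ci_high     p
#>      INFORMATIVE 0.981 0.0988    9.74 0.987
#>    INSTRUCTIONAL 1.436 0.1435   14.37 0.758
#>     MOTIVATIONAL 2.222 0.2191   22.54 0.499
#>       SUPPORTIVE    NA     NA      NA    NA
#>     NOTIFICATION 2.952 0.2873   30.34 0.362
```

At 142 replies the intervals are wide and the SUPPORTIVE row is `NA` — no
stop reply followed a supportive message in this small corpus, and the
package refuses to report estimates from degenerate fits rather than
returning separation artifacts. Odds-ratio recovery at realistic event
counts is demonstrated by the acceptance script below (~12,000 reply
events per replicate). Per-participant outcomes, rendered reports and CSV
artifacts come from `report$outcomes`, `render_report(report, "markdown")`
and `write_report_artifacts(report, dir)`; a thin command-line wrapper
over the same functions is at `inst/cli/smsengage.R`.

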