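---
title: "Entity-conditioned do-calculus screening over text: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entity-conditioned do-calculus screening over text: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causaltext)
```

## The model

`causaltext` screens biomedical named entities for association with a binary
clinical endpoint expressed in free text. The pipeline composes four
estimators:

1. **Endpoint labeling.** Each sentence $x_i$ inherits the endpoint label of
   its source record: positive when the record's expert likelihood category
   is A (well known) or B (known/highly likely), negative otherwise.
   Sentences that state the likelihood score itself must be excluded by the
   caller (an `exclude` flag on the input), since they encode the label
   verbatim.

2. **Conditional-probability estimation.** A probabilistic classifier
   supplies $p(x_i) = \hat P(\text{endpoint} \mid x_i)$ for *every* sentence
   of the corpus, trained on a 9:1 stratified split and selected by minimum
   held-out cross entropy over periodic checkpoints.

3. **Do-contrast.** For an entity $e$, the prediction table is partitioned
   by observed presence: $S_1 = \{p(x_i) : e \in x_i\}$ and
   $S_2 = \{p(x_i) : e \notin x_i\}$. The interventional reading
   $P(\text{endpoint} \mid \mathrm{DO}(e))$ is operationalized as the mean
   of $S_1$; no counterfactual text editing is performed. The one-tailed
   two-sample z-statistic
   $z = (\bar S_1 - \bar S_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ (unbiased
   sample variances) is referred to the upper standard-normal tail, and
   p-values are Benjamini–Hochberg adjusted across entities. An entity with
   adjusted $p < \alpha$ (default 0.05) is an *enriched causal term*. A raw
   z-threshold mode (default 1.645) is available for pseudocode-style
   screening.

4. **Clinical use.** Enriched terms, minus excluded drug entities, populate
   a knowledge-based causal tree under the seven ACG causal-factor
   categories. Patients are stratified by the R score — here the plain
   ratio ALT/AST (U/L over U/L) — into hepatocellular ($R > 5$), mixed
   ($2 \le R \le 5$) and cholestatic ($R < 2$) injury patterns, plus a
   severity bucket derived from matched clinical-outcome terms.

### Assumptions

The do-contrast is *observational*: it identifies entities whose presence
shifts the classifier's conditional endpoint probability upward. Causal
language is warranted only to the extent that (i) the classifier estimates
$P(\text{endpoint}\mid x)$ faithfully, and (ii) entity presence is not
confounded with other endpoint-associated text features. Neither confounder
adjustment nor collider detection is attempted; this is a screening tool,
and the z-test's null is "no difference in predicted probability", not "no
causal effect" in the structural sense.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `train_fraction` | 0.9 | — | 9:1 stratified split |
| `freq_threshold` | 50 | sentences | entities must occur in **more than** 50 sentences (strict) |
| `alpha` | 0.05 | — | adjusted-p cutoff for enrichment |
| `min_group` | 5 | sentences | smallest group for the normal approximation |
| `adjust_method` | BH | — | field-standard FDR control; Holm/Bonferroni available |
| `l_max` | 30 | ranks | POT curve cut range |
| `n_runs` | 3 | — | parallel repeats for robustness, varying only the classifier seed |
| `l1_relax` | 1.0 | — | multiplier on the per-feature universal soft-threshold (below) |
| `l2` | 1e-4 | — | small ridge for numerical stability |
| `training_steps` | 600 | steps | full-batch proximal gradient budget |
| `checkpoint_interval` | 25 | steps | held-out loss recorded for early stopping |

The transformer-era hyperparameters (sequence length 128, batch 128, 2,500
steps, 500-step warmup, checkpoints every 200) are preserved in
`transformer_reference_config()` for adapters that wrap a language model
behind the same contract; the desk-scale default ignores them.

## Why the default classifier is sparse

The default classifier is a linear model over token counts with logistic
output, fit by full-batch proximal gradient descent on the penalized binary
cross entropy. Three design elements matter, and all three exist for the
*downstream test*, not for classification accuracy:

* **Intercept initialization at the base-rate logit.** Starting from
  $p = 0.5$, every token weight absorbs a share of the downward intercept
  correction in proportion to its frequency; sentences mentioning an entity
  then differ systematically from the rest, and the do-contrast detects the
  artifact. Initializing $b = \mathrm{logit}(\bar y)$ removes the drift.

* **Per-feature universal soft threshold.** A dense fit leaves sampling
  noise of order $\sqrt{\overline{c_t^2}\,\bar p(1-\bar p)/n}$ on every
  token weight. For a rare entity token, that noise is a *real* difference
  between the DO and NOT-DO prediction means, so the z-test finds it: in a
  no-signal corpus the entity-wise z statistics are then badly
  overdispersed even though the test itself is exactly calibrated for
  membership-exchangeable subsets. Soft-thresholding each weight at
  `l1_relax` times the universal threshold
  $\sqrt{2\log V \cdot \overline{c_t^2}\,\bar p(1-\bar p)/n}$ zeroes
  gradients that are statistically indistinguishable from noise while
  letting genuine effects through (their gradients exceed the threshold by
  construction of any usable effect size). The multiplier 1.0 — the exact
  universal-threshold scale — was fixed once, after a calibration
  experiment on no-effect corpora, and is deliberately not exposed as a
  tuning dial in the pipeline configuration.

* **An unpenalized sentence-length covariate.** Under a pure null the
  thresholded fit would otherwise collapse to a constant predictor, for
  which the z-test is undefined (zero variance). Standardized sentence
  length is a benign, entity-exchangeable covariate that keeps the
  prediction table non-degenerate; under signal its coefficient is free to
  vanish.

Training uses backtracking line search, so the penalized objective is
non-increasing step to step; the best checkpoint by held-out loss is
returned (the untrained initial point is recorded but never selectable).

## The synthetic generator

The generator emulates the token statistics of a sentence corpus extracted
from drug-safety monographs: truncated-normal sentence lengths (mean 26.84,
SD 15.58 tokens, floor 3), a Zipf filler vocabulary (default 2,000 words),
and 60 entities (10 drugs, 10 genes, 40 diseases) inserted as surface-form
token spans with inclusion probability 0.03 each — giving corpus
frequencies comfortably above the screening floor of 50 at the default
5,000 sentences. Labels follow a logistic structural model
$y_i \sim \mathrm{Bern}(\sigma(b + \sum_e \beta_e \mathbf 1[e \in x_i]))$
with $\beta = 4$ on 10 planted entities by default; the intercept $b$ is
solved exactly (enumeration over the planted-inclusion distribution) so the
marginal positive rate equals 0.249. Because the model is logistic, the
true interventional contrast has a closed form (`analytic_effects()`),
giving the causal engine an oracle. Spans are inserted as atomic units:
a mention is never split by a later insertion, so detectability does not
depend on sentence length — an artifact that would otherwise bias the
do-contrast through the length covariate.

What the generator does *not* emulate: discourse structure, section
layout, synonymy beyond simple alternate surface forms, label noise from
imperfect expert categories, and confounded entity co-occurrence (entities
are included independently). Passing tests on synthetic corpora therefore
demonstrate statistical correctness of the machinery, not robustness to
real-world confounding.

Patient cohorts are generated with labs covering the three R regimes
(AST log-normal around 80 U/L, ALT = R·AST) and case-report text embedding
a clinical-outcome term of the sampled severity band, so expert labels are
recoverable by construction.

## Numerical choices

* **idf logarithm**: natural log, switchable; `idf = log(N/(df+1))`, which
  is negative when a term occurs in every document — reported as-is.
* **Tokenization**: lowercase, split on non-alphanumeric runs, numerals
  kept. Deterministic and identical for corpus and lexicon.
* **Sentence splitting**: rule-based on `.!?` + whitespace + capital/digit,
  with decimal-number and abbreviation guards; no model dependency.
* **Split rounding**: per-class *train* count is
  `floor(class_n * train_fraction)`, remainder to test. On 14,361 sentences
  with 3,578 positives at 0.9 this gives 12,924 / 1,437 — the canonical
  9:1 sizes. (A round-half rule on the test count would give 12,925.)
* **Pattern-rule boundaries**: $R = 2$ and $R = 5$, unclassified under the
  strict published inequalities, are folded into "mixed" so the rule is
  total; configurable.
* **R score definition**: ALT/AST as published for this pipeline;
  `r_score_uln()` provides the ULN-normalized ALT/ALP variant that clinical
  guidelines use, off by default.
* **Loss clipping**: probabilities clipped at $10^{-12}$ in the cross
  entropy.
* **Ties in ranked term lists**: broken lexicographically by entity id, so
  repeated runs rank deterministically.
* **Venn commonality**: intersection over union of the runs' enriched
  sets.
* **POT with short lists**: a run with fewer than $L$ enriched terms
  contributes its full list, so POT(L) decays like $|{\rm list}|/L$ beyond
  the list length.
* **Severity buckets**: liver-failure outcomes map to bands 4–5,
  structural damage (cirrhosis, sinusoidal obstruction syndrome) to 3,
  jaundice/hypersensitivity to 2, rash to 1; fully configurable
  (`default_severity_map()`), since no published rule pins this mapping.

## Test problem sizes

The test suite exercises the pipeline at 5,000-sentence corpora: 20
no-effect corpora with 200 entities for null calibration, 10 strong-effect
corpora (10 planted of 60, $\beta = 2$) for recovery, and 120–175-patient
cohorts for stratification; unit tests use corpora of 400–2,500 sentences.
These sizes give the Monte-Carlo checks standard errors small enough to be
decisive while keeping a full run in minutes on one core.

## Known limitations

* The do-contrast cannot distinguish causes from confounders or colliders;
  enriched terms are candidates, not established mechanisms.
* Screening validity rests on the sparse-fit calibration argument above;
  swapping in a dense or overparameterized classifier (including a
  transformer adapter) re-introduces anticonservativeness under the null,
  and should be paired with a permutation check.
* The gazetteer matches exact token subsequences only; morphological
  variants or misspellings require explicit synonym rows.
* R = ALT/AST follows the published pipeline but is *not* the clinical
  R value (ALT/ULN over ALP/ULN); interpret the pattern labels
  accordingly.
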