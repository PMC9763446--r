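# causaltext

Entity-conditioned causal screening over free-text corpora, with an
application to idiosyncratic drug-induced liver injury (iDILI) patient
stratification.

## The problem

Narrative drug-safety resources (drug monographs, case reports) encode which
clinical factors travel with an adverse endpoint, but the evidence is locked
in prose. `causaltext` implements a desk-scale pipeline that screens
biomedical named entities for a causal association with a binary endpoint
using an interventional (do-operator style) contrast:

1. **Corpus**: documents are split into sentences; each sentence `x_i`
   receives an endpoint label `y_i` (for the liver-injury application,
   positive iff its source drug record carries likelihood category A or B).
2. **Classifier**: a probabilistic text classifier estimates
   `p(x_i) = P(endpoint | x_i)` for every sentence. The default is a sparse
   bag-of-words logistic model trained by proximal gradient descent on the
   binary cross entropy; any classifier honoring the
   `fit` / `predict_probability` contract (e.g. a fine-tuned transformer)
   can stand in.
3. **NER**: a deterministic gazetteer extracts entity mentions
   (drug / gene / disease), keeping entities mentioned in more than 50
   sentences.
4. **Do-contrast**: for each entity `ner`, the prediction table is
   partitioned into `S1 = {p(x_i) : ner in x_i}` (DO) and
   `S2 = {p(x_i) : ner not in x_i}` (NOT-DO), compared with a one-tailed
   two-sample z-test

   `z = (mean(S1) - mean(S2)) / sqrt(var(S1)/n1 + var(S2)/n2)`,

   and entities with Benjamini-Hochberg adjusted p < 0.05 are reported as
   enriched causal terms.
5. **Robustness**: repeated runs (same data, different classifier seed) are
   compared by the percentage of overlapped terms, `POT(L) =
   |intersection of each run's top-L terms| / L` averaged over `L = 1..30`,
   and by the Venn commonality (intersection over union) of the enriched
   sets.
6. **Causal tree & stratification**: enriched terms are organized into the
   ACG clinical-guideline factor categories; patients are stratified by the
   R score (ALT/AST) into hepatocellular (R > 5), mixed (2 <= R <= 5) and
   cholestatic (R < 2) injury patterns, with a severity bucket from matched
   clinical-outcome terms.

A synthetic-corpus generator with a logistic structural model over planted
entities provides ground truth, so the whole pipeline is testable offline;
see `vignettes/entity-do-calculus.Rmd` for the model, its assumptions, and
the numerical design choices.

## Worked example

```r
library(causaltext)

sim   <- generate_corpus(generator_config(n_sentences = 5000, seed = 1))
sp    <- stratified_split(sim$corpus, 0.9, seed = 1)
model <- fit_text_classifier(sp$train, training_config(seed = 1))
preds <- predict_corpus(model, sim$corpus)
occ   <- frequency_filter(build_occurrence(sim$corpus, sim$lexicon), 50)
tab   <- infer_causal_terms(sim$corpus, preds, occ)
print(tab)
recovery_metrics(tab$enriched, sim$truth)
```

which prints

```
<text_corpus> 5000 instances (1277 positive, 0.255 positive rate)
<causal_table> 60 tested, 10 enriched (alpha 0.05, BH), 0 skipped
    entity    z   p_value adjusted_p mean_do mean_not_do probability_difference
 disease40 36.4 4.74e-291  2.84e-289   0.650       0.242                  0.408
    gene04 33.3 3.17e-243  9.50e-242   0.668       0.242                  0.426
    ...
precision 1.00 recall 1.00 against planted truth
```

The corpus has a 0.255 positive rate (target 0.249); the classifier reaches
held-out accuracy 0.886; exactly the 10 planted causal entities are
enriched (`mean_do` is the average predicted endpoint probability among
sentences mentioning the entity, `mean_not_do` among the rest, and their
difference is the estimated interventional contrast).

Patient stratification on a synthetic cohort:

```r
cohort <- generate_cohort(175, seed = 1)
strat  <- stratify_cohort(cohort, example_clinical_tree(), clinical_lexicon())
concordance(strat$r, vapply(cohort, function(p) p$alt / p$ast, numeric(1)))
#> [1] 1
```

A thin command-line wrapper is included:

```sh
Rscript inst/cli/causaltext.R run --seed 3 --out run_dir
Rscript inst/cli/causaltext.R simulate --seed 5 --out sim_dir
```

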