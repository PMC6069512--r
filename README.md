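# supstatus

Sentence-level classification of **dietary-supplement use status** in
clinical text. Given a sentence that mentions a target supplement
(ginkgo, fish oil, St John's wort, ... — 25 commonly used supplements
are packaged), the package assigns one of four statuses:

| class | meaning | example |
|---|---|---|
| C | Continuing | "Continue fish oil to reduce inflammation." |
| D | Discontinued | "The Ginkgo biloba was discontinued on admission." |
| S | Started | "Started echinacea 1 week ago for cold." |
| U | Unclassified (advice, inquiry, avoidance) | "Pt inquiring about milk thistle." |

Use-status extraction is the gateway to supplement pharmacovigilance:
drug–supplement interactions (e.g. ginkgo–warfarin bleeding) only matter
for supplements a patient is actually taking, and that fact usually
lives in free-text notes rather than the structured medication list.

The package provides two complete classifiers over one preprocessing
pipeline, and everything needed to evaluate and compare them:

* **Rule engine** — status-indicator lemmas ("start", "stop", "hold",
  "recommend", ...) matched within a token window *W* (default 7) on
  either side of the supplement mention, with negation handling
  ("never stopped" ⇒ still taking), a governing rule for weak intake
  verbs ("stop *taking*", "recommend *taking*"), nearest-indicator
  resolution, and a window-size sweep.
* **Learning harness** — nine feature-set types (raw/normalized
  unigrams, TF-IDF, bigram/trigram combinations, windowed indicator
  features) crossed with five classifier families (decision tree,
  random forest, multinomial naive Bayes, maximum entropy = multinomial
  logistic regression, linear SVM), with stratified 10-fold
  cross-validated hyperparameter selection.
* **Evaluation** — per-class and support-weighted precision/recall/F
  (weighted metric = Σ n\_c·m\_c / Σ n\_c), confusion matrices, Cohen's
  kappa (κ = (p\_o − p\_e)/(1 − p\_e)), per-supplement breakdowns,
  pairwise classifier comparison cells, and automated rule-error
  categorization (missing-pattern / indicator-issue / distance-issue).
* **Synthetic corpus generator** — a seeded, template-based stand-in
  for the protected clinical corpus: 25 supplements × 100 sentences,
  realistic class mix, controlled indicator–mention distances,
  abbreviations ("cont", "d/c"), misspelled variants, negations and
  distractor co-mentions. Generated labels are rule-recoverable by
  construction, so end-to-end tests are meaningful.

## Worked example

```r
library(supstatus)

lex  <- load_lexicons()                       # 25 supplements, 28 indicators
corp <- generate_corpus(generator_config(seed = 42), lex)   # 2500 sentences
sp   <- split_corpus(corp, seed = 7)          # 1750 train / 750 test

## rule-based classifier at the default window of 7
pred_rb <- classify_corpus(sp$test, lex, rule_config())
score(sp$test$label, pred_rb)
#> <evaluation_report> n = 750
#>  class support precision recall f_measure
#>      C     275      1.00   1.00      1.00
#>      D     149      1.00   0.99      1.00
#>      S     176      1.00   1.00      1.00
#>      U     150      0.99   1.00      0.99
#> Total (weighted): P 1.00  R 1.00  F 1.00

## maximum entropy over feature type 8 (uni + bi + windowed indicators)
cfg <- train_config("maximum-entropy", feature_spec(8), folds = 10, seed = 11)
mod <- train_model(sp$training, cfg, lex)
mod
#> <sup_model> maximum-entropy, feature type 8, lambda = 0.01 (CV weighted F 0.962), seed 11
score(sp$test$label, predict(mod, sp$test, lex))
#> <evaluation_report> n = 750
#>  class support precision recall f_measure
#>      C     275      0.98   0.95      0.96
#>      D     149      0.91   0.98      0.94
#>      S     176      0.95   1.00      0.97
#>      U     150      1.00   0.92      0.96
#> Total (weighted): P 0.96  R 0.96  F 0.96
```

The per-class rows are precision/recall/F over the held-out synthetic
test split; the totals are support-weighted means. Synthetic sentences
are far more regular than clinical prose, so these scores characterize
pipeline recovery, not clinical performance (see the methods vignette).

Single sentences work too:

```r
ts <- preprocess_sentence("He never stopped taking the saw palmetto.", lex)
m  <- find_mentions(ts$raw_tokens, lex$supplements)[1, ]
classify_sentence(ts, m, lex$indicators, rule_config())
#> [1] "C"
```

A thin command-line front end ships in `inst/exec/supstatus`
(`generate`, `split`, `classify-rules`, `sweep-window`, `featurize`,
`train`, `predict`, `grid`, `evaluate`, `compare`, `agreement`).

## Package layout

```
R/lexicons.R     lexicon I/O, supplement-mention matching
R/preprocess.R   abbreviation expansion, tokenizer, surrogate normalizer
R/corpus.R       corpus container + line-delimited JSON I/O
R/rule_engine.R  windowed indicator matching, negation, sweep
R/features.R     the nine feature-set types, TF-IDF, vectorizer
R/models.R       five learner families, CV grid selection, grid report
R/evaluate.R     scoring, kappa, comparison, error categorization
R/syncorpus.R    synthetic corpus generator and 70/30 splitter
inst/extdata/    editable lexicon and template data files
```

See `vignettes/use-status-classification.Rmd` for the model, its
assumptions, parameter choices and limitations.
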