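---
title: "Classifying dietary-supplement use status in clinical sentences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dietary-supplement use status in clinical sentences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supstatus)
```

## The problem

Clinical notes carry most of what is recorded about dietary-supplement
use — substances like ginkgo, fish oil or St John's wort that interact
with prescription drugs (ginkgo–warfarin bleeding being the classic
example) but are absent from structured medication lists. For
pharmacovigilance, knowing *whether a patient is actually taking* a
supplement matters as much as the mention itself. `supstatus` classifies
a sentence containing a target supplement mention into one of four use
statuses:

* **C — Continuing**: the patient is (still) taking it ("Continue fish
  oil to reduce inflammation").
* **D — Discontinued**: intake has stopped ("The ginkgo biloba was
  discontinued on admission").
* **S — Started**: intake has just begun ("Started echinacea 1 week ago
  for cold").
* **U — Unclassified**: advice, recommendation, inquiry or avoidance —
  anything that does not assert current intake ("Pt inquiring about milk
  thistle").

The package implements two complete classifiers over the same
preprocessing — a window-based indicator rule engine and a supervised
learning harness — plus the evaluation machinery to compare them, and a
seeded synthetic-sentence generator that stands in for the clinical
corpus such work is normally developed on, which cannot be shared.

## Preprocessing

Sentences are lowercased; clinical abbreviations are expanded to their
full forms before anything else ("cont" to "continue", "d/c" and
"d/ced" to forms of "discontinue") so that slash-bearing shorthand is
still one token when the expansion map is consulted. Tokenization splits
on whitespace and strips leading/trailing characters outside
`[a-z0-9']`; a bare en-dash therefore disappears while "d/c" and
"john's" survive intact.

Normalization then removes stop words, pure-digit and pure-punctuation
tokens, deletes residual digits and punctuation inside tokens, and maps
every remaining token to a canonical lexical form. The normalizer is a
surrogate for a full lexical-variant tool: an exception dictionary
("took" to "take", "held" to "hold") backed by a conservative suffix
stripper (-s/-es/-ies, -ed, -ing) that restores a stripped final "e"
when the result is a known lemma ("continu" to "continue") and refuses
stems shorter than three characters. This collapses exactly the
inflectional variation the classifiers care about; full derivational
normalization is out of scope. Two cleaned layers are kept — with and
without lemmatization — because raw-unigram features (type 1) are
defined on unlemmatized tokens.

One important exception: tokens belonging to a supplement-lexicon
variant are exempt from removal and normalization. "e" in "vitamin e"
would otherwise be discarded as noise and "q10" in "coenzyme q10" as a
digit-bearing token, destroying the very mention the classifier anchors
on.

## The rule engine

Status-indicator lemmas (28 in the packaged lexicon) each carry one
class: "continue"/"increase"/"take" are C, "stop"/"hold"/"off" are D,
"start"/"add"/"resume" are S, "recommend"/"avoid"/"suggest" are U. An
indicator fires when it lies within a window of at most *W* tokens of
the target mention on the normalized layer, on either side; *W*
defaults to 7. Matching on lemmas means "started", "starting" and
"starts" all hit "start".

When several indicators fire, the engine resolves deterministically:

1. **Negation**: a negator ("no", "not", "never", "decline", "deny")
   within 2 tokens before an indicator remaps it — a negated D becomes C
   ("never stopped" means still taking), a negated C or S becomes U.
2. **Governing**: the weak intake verbs "take", "use" and "try" adopt
   the effective class of an indicator within 2 tokens before them.
   This is the design decision the golden sentences forced: in "stop
   taking ginger", "recommend taking fish oil" and "consider trying otc
   ginkgo" the weak C verb always sits *closer* to the mention than the
   real status indicator, so no pure nearest-indicator policy can
   classify them; treating the preceding indicator as governing the
   infinitive resolves all of them without breaking any other example.
3. **Resolution**: smallest distance wins; ties prefer an indicator
   before the mention; residual ties follow the precedence U > D > S > C.
4. **Default**: with no match at all, the sentence is Unclassified.

The window default of 7 is deliberately not the arg-max of the window
sweep: the sweep (`sweep_window()`) shows F rising steeply to a plateau
around 6 tokens, and a slightly larger fixed window is kept to avoid
tuning into the training data. Distance is measured on normalized
tokens; the raw-token distance would differ by the number of
intervening stop words.

```{r rules}
lex <- load_lexicons()
g <- golden_sentences()
pred <- classify_corpus(g, lex, rule_config())
table(gold = g$label, predicted = pred)
```

## Feature sets and learners

Nine feature-set types are built from the tokenized sentences: raw
unigrams (1), normalized unigrams (2), TF-IDF-weighted unigrams (3),
bigrams (4), unigram+bigram (5) and unigram+bigram+trigram (6)
combinations, indicator features alone (7), and types 5/6 augmented
with indicator features restricted to a 6-token window (8, 9). N-gram
features carry counts; indicator features are binary presence flags,
direction-agnostic, with distance entering only through the window
cut-off (type 7 uses the whole sentence — no cut-off is listed for it).
A flagged variant additionally encodes bucketed distances for readers of
the feature-type list who take "with distance" to mean distance values;
it is off by default. TF-IDF uses the smoothed formula
`tf * (ln((1+N)/(1+df)) + 1)` with L2 row normalization, so a term
present in every document keeps a floor weight of 1 and no division can
blow up; the exact formula is a package choice, documented because
"TF-IDF" alone underdetermines it.

Vocabularies are fixed on the training split only; unseen test features
are dropped. Five classifier families run over any feature set, through
the packages an R practitioner would reach for — rpart (decision tree),
ranger (random forest), glmnet multinomial ridge (maximum entropy, i.e.
L2-regularized multinomial logistic regression), e1071 (linear-kernel
SVM) — plus a multinomial naive Bayes with additive smoothing
implemented in the package, since the installed naive Bayes
implementations are Gaussian rather than the count-model variant text
classification uses.

Hyperparameters are selected by stratified 10-fold cross-validated
weighted F on the training split, over small conventional grids (tree
depth 5/10/30, forest size 100/300, smoothing 1.0/0.1, ridge penalty
10/1/0.1/0.01, SVM cost 0.1/1/10), ties resolving to the simplest
point. Nested grids share fits: one regularization path per fold covers
every ridge penalty, one deep tree per fold is snipped back to each
depth (greedy top-down growth makes the depth-5 tree exactly the top of
the deep tree), and one 300-tree forest per fold is evaluated at 100
trees by truncating the ensemble. The SVM is left uncalibrated and
predicts labels only.

## Evaluation

`score()` reports per-class precision, recall and F with the 4x4
confusion matrix; "Total (weighted)" metrics are support-weighted
arithmetic means of the per-class values — stated explicitly because
"weighted" could otherwise mean micro-averaging. Display rounding is
half-up. Cohen's kappa uses the marginal-product chance model.
`compare_classifiers()` produces the per-class both-right /
A-only / B-only / both-wrong cells whose sums reconstruct each
classifier's true positives. `categorize_errors()` automates the error
review with three mutually exclusive categories applied in order:
*missing-pattern* (no indicator anywhere, or nothing else explains the
miss), *indicator-issue* (competing indicators of different classes
inside the window), *distance-issue* (a gold-class indicator exists
only beyond the window). The precedence is a package convention; a
manual review could reasonably assign borderline sentences differently.

## The synthetic corpus

The generator emulates the study conditions: 25 supplements x 100
sentences (2500 total), class mix C .3348 / D .1956 / S .2412 / U .2284
(the pooled train+test class counts), split 70/30 within each
supplement to 1750/750. Sentences are assembled from a template bank in
which every published example sentence appears with its supplement slot
abstracted, plus paraphrase variants marked `synthetic` in the data
file. Each template places its indicator at a controlled token distance
from the mention: a filler slot is expanded with content words that
survive normalization one-for-one, so the generated distance is exact.
Distances follow a truncated geometric law (decay 0.6, maximum 10),
putting most indicators within a few tokens but leaving a small tail
beyond the default window — which is what makes the rule engine's rare
distance-issue errors appear at realistic (sub-percent) rates.

Perturbations apply per sentence at fixed rates chosen once as
plausible for clinical text: abbreviation 0.15 (clinical shorthand is
pervasive), misspelled supplement variants 0.15, negation 0.05,
distractor co-mentions 0.10. A negated sentence is constructed from a
*source* class so that its final label is the sampled one ("never
stopped X" is built as a D-template realizing C); sampling final labels
keeps the class mix at the configured proportions independent of the
negation rate. Distractor clauses append a non-lexicon substance with a
different-status indicator placed strictly farther from the target
mention than the target's own indicator, so nearest-indicator
resolution is unaffected.

By construction, the stored label of every generated sentence is what
the rule engine recovers at unbounded window — the invariant the test
suite checks over the full corpus, and the property that makes
end-to-end learning tests meaningful: a learner that recovers the
labels has genuinely learned the indicator-window structure.

What the generator does **not** emulate: the lexical diversity, section
structure, and annotation ambiguity of real clinical notes. Template
sentences are far more regular than clinical prose, so absolute scores
on the synthetic corpus run higher than any clinical-corpus result and
should be read as pipeline-recovery checks, not as performance claims
about real notes.

## Numerical and design choices

* Distances, windows and alignment are all defined on the normalized
  token layer; mention tokens are protected so a mention always
  survives.
* Variant matching strips apostrophes and periods on both sides
  ("st. john's wort" equals "st johns wort") and prefers the longest
  variant, so multi-token names never produce partial matches; a
  variant string claimed by two supplements is rejected at load time as
  unresolvable.
* Classes are ordered C, D, S, U everywhere; argmax ties in learner
  probabilities resolve to the first class in that order.
* Degenerate feature spaces (an indicator feature set over a corpus
  with no indicators) are padded with constant zero columns, and a
  majority-prior fallback stands in where a fitter cannot run on an
  all-zero matrix.
* All randomness (generation, splitting, fold assignment, forests)
  flows from explicit integer seeds; identical configuration and seed
  reproduce results bit for bit, and RNG state of the calling session
  is restored.

## Problem sizes

The packaged defaults are the study-scale conditions: 2500 generated
sentences, 1750/750 split, 10-fold cross-validation, the full 5
algorithm x 9 feature-type grid. These sizes run end to end in minutes
on a single CPU; unit tests use smaller corpora (10 sentences per
supplement) where the full scale adds nothing to the property being
checked.

## Limitations

The rule inventory is the packaged indicator lexicon, not the original
(unpublished) 68-rule set; the supplement variant lists beyond the
published ginkgo example are implementer-supplied data files and
editable as such. Cross-sentence context, temporal resolution of status
changes, and note-section awareness are out of scope, as are word
embeddings and neural classifiers. Scores on the synthetic corpus
characterize the implementation, not clinical performance.
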