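---
title: "Mapping pathology synopses to semantic labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pathology synopses to semantic labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(synoptic)
```

## The problem

A bone marrow aspirate synopsis is a semi-structured report: an ordered list
of `field: description` pairs (cellularity, erythropoiesis, granulopoiesis,
megakaryocytes, lymphocytes, a free-text comment) whose semantic content a
hematopathologist compresses into a handful of diagnostic concepts —
"normal", "acute myeloid leukemia", "hypercellular", and so on. A case may
warrant several such labels at once, labels are wildly imbalanced in
practice, and the label set itself is not fixed in advance: new concepts
surface as experts read more cases. `synoptic` implements an end-to-end
pipeline for this setting:

* a **binary-relevance (BR) multi-label classifier** over text embeddings,
  with a sigmoid score per label and a fixed decision threshold;
* **field-order shuffle augmentation**, exploiting that the order of a
  synopsis's fields carries no meaning;
* a **rare-label active-learning loop** (CRL sampling: *cases with rare
  labels*) that grows a labeled development set and discovers new labels
  against a pluggable labelling oracle;
* an **adapted Monte Carlo cross-validation** splitter that guarantees every
  label a minimum presence in validation;
* **word-knockout interpretability** and **embedding-space analyses**; and
* a **synthetic synopsis generator** with planted ground truth, so every
  stage is testable without access to protected clinical text.

## Model

Each synopsis is serialized to a single string of `field: description`
segments joined by `"; "`. The built-in encoder is a *feature-hashing*
encoder: case-folded, punctuation-stripped word tokens and consecutive-token
bigrams are hashed into a fixed number of buckets (default 1024) and the
count vector is L2-normalized. A trainable projection
`z = tanh(W1 x + b1)` (default width 64) produces the *classification
embedding*; a dropout layer (rate 0.5 during training) and a linear head
yield one logit per label, mapped to a score in (0, 1) by the sigmoid
`S(x) = 1 / (1 + e^{-x})`. Labels are treated independently (binary
relevance): the loss is the weighted binary cross-entropy

```
l_n = -w_n [ y_n log σ(x_n) + (1 - y_n) log(1 - σ(x_n)) ]
```

averaged over labels within an item and over items in a batch, with
per-label weights `w_n` defaulting to 1. Optimization is decoupled-weight-
decay Adam (AdamW; weight decay applies to the weight matrices, not the
biases). One snapshot is taken per epoch and the snapshot with the highest
*validation micro-average F1* is returned; ties go to the earliest epoch for
reproducibility. The head bias is initialized at the per-label training
prior logit, the standard starting point for imbalanced binary-relevance
heads.

Two encoder-design points deserve explanation:

* **Bigrams are down-weighted** (`bigram_weight`, default 0.1). Within-field
  token sequences are nearly unique per case, so full-weight bigram features
  act as case fingerprints: the network can drive the training loss to zero
  by memorizing cases without ever using the planted class evidence, which
  shows up as a large train/validation gap. Down-weighting keeps bigrams as
  a mild order-sensitive signal (without them, field-shuffle augmentation
  would be a no-op for a pure bag encoder) while the unigram evidence
  dominates learning.
* **Two training presets.** `train_config()`'s defaults (learning rate 1e-3,
  weight decay 1e-2, 10 epochs, head dropout 0.5, batch 16) are the recipe
  appropriate for *fine-tuning a large pretrained encoder*, where small
  steps over few epochs suffice. The hashing backend trains from random
  initialization, and first-order optimizers with per-parameter step
  normalization move each weight by roughly (learning rate × steps); at
  1e-3 over 10 short epochs that movement budget is far below the logit
  swing a confident prediction needs. `lightweight_config()` is therefore
  the documented recipe for the built-in backend: learning rate 1e-2,
  batch 4, 20 epochs, plus input-feature dropout 0.15 as extra protection
  against token-combination memorization. Everything else (loss, AdamW,
  best-epoch selection, augmentation) is identical between the presets.

## Augmentation

Because a synopsis is semantically a *set* of fields, any permutation of the
fields is a faithful re-rendering. During training, each case is serialized
under `train_views` (default 3) freshly sampled permutations every epoch —
an augmentation that perturbs exactly the order-sensitive (bigram) features
while preserving the token multiset. At prediction time,
`augmented_predict()` scores `predict_views` (default 5) permutations and
takes the element-wise **maximum** per label, so each aggregated score
dominates every single view. Mean aggregation is available behind a flag but
off by default. Permutations are drawn without replacement whenever the
requested number of views does not exceed the number of distinct orders;
beyond that they repeat, with a warning. View counts are design choices —
the mechanism, not the counts, is the point — and both are configuration.
Whether training augmentation is a one-time dataset expansion or a per-epoch
resampling is an open interpretive question; per-epoch resampling was chosen
because it maximizes view diversity at no storage cost.

## Splits

During the active-learning stage, a model must know *every* current label to
sample for it, so `al_stage_split()` first assigns at least one case per
label to training and then splits the remainder randomly to an overall
80/20. After the development set stabilizes, `mccv_split()` implements the
adapted Monte Carlo cross-validation: with
`min_val_per_label = floor(min(label count) × ratio)`, a first pass over the
shuffled cases routes any case carrying an under-represented label to
validation; a reshuffled second pass fills validation to `n × ratio`. The
floor is taken because the procedure's guarantee must be satisfiable for
every label (the rarest label cannot contribute more validation cases than
`count × ratio` rounded down); when the rarest label is so small the floor
is 0, that is logged rather than hidden. If the first pass overfills
validation the overfill stands — the procedure has no removal step.
`repeat_mccv()` produces the independent splits behind an ensemble of final
models whose validation scores are reported as mean ± spread.

## Active learning

The loop (`run_active_learning()`) seeds the labeled set with 50 randomly
sampled oracle-labeled cases, then iterates: train on the current labeled
set (via the stage split), score the unlabeled pool, and for every *rare*
label — labeled count strictly below the working threshold — sample
`threshold − count` pool cases from that label's predicted group, uniformly
at random. Candidates are deduplicated with the rarest label claiming cases
first. If the candidate set exceeds the cap (100), the working threshold
drops by 5 and sampling repeats, so no single review round overwhelms the
annotator. Verified answers join the labeled corpus; labels the vocabulary
has not seen are appended (never reordered), which is how *label discovery*
happens: hidden concepts surface when a case carrying them is reviewed for
some other reason. The threshold schedule is `c(10, 15, 20)` — lowered
thresholds in the early iterations, 20 thereafter — and the loop terminates
when no label is rare at the final threshold.

Two engineering decisions make the loop robust at desk scale:

* **Rank fallback.** "Predicted group" is numerically undefined for a model
  that has seen two cases of a label: no pool case may cross the 0.5
  threshold even though the model already *ranks* true cases of that label
  near the top. When a predicted group is smaller than the request,
  `sample_crl()` fills the remainder with the highest-scoring unclaimed
  cases. Without this the loop starves on exactly the labels it exists to
  enrich; with it, two examples are enough to bootstrap a label to its
  threshold in a few iterations.
* **Stall accounting.** A rare label whose count does not move for three
  consecutive iterations at the final threshold is treated as
  pool-exhausted, excluded from further sampling, and reported in
  `$shortfall` — the loop terminates with an explicit report instead of
  looping forever when the pool simply cannot supply a label.

For budget-matched comparisons against random sampling, `grow_to_budget`
keeps raising the threshold by 5 once the set is balanced, until the
labeling budget is spent — the natural continuation rule when further
annotation is judged worthwhile. The comparison's fixed benchmark is the
validation part of an adapted-MCCV split of the AL-built development set:
an *enriched* benchmark in which rare labels carry real weight. The package
ships a synthetic oracle (below) and a file-based oracle that exchanges
`candidates.csv` / `verified.csv` with a human reviewer.

## Evaluation

`confusion_counts()` tallies each label as an independent binary decision;
`eval_metrics()` derives per-label precision, recall and F1, their
micro-averages from the summed counts (micro-F1 weighs every (case, label)
decision equally, so it tracks the common labels by construction), and a
macro row for diagnostics only. A 0/0 quotient is reported as 0 and flagged
`degenerate`, which penalizes empty predictions rather than inflating
scores. `learning_curve()` trains on nested prefixes (batches of 50 by
default) against one fixed benchmark and reports mean ± standard error over
seeds.

## Word knockout

`knockout_case()` removes every occurrence of one word from the descriptions
and subtracts the new scores from the originals — since nothing else
changes, the difference is the word's influence. Knockout operates on the
canonical (stored-order, unaugmented) serialization so the word is the only
varying factor, and on whitespace-delimited, punctuation-stripped,
case-folded words rather than encoder sub-tokens, because "a word" is the
unit a reader reasons about. `influence_table()` sums signed deltas over all
labeled cases containing the word, grouped by each case's *gold* labels, and
divides each word's per-label sums by the L2 norm of its across-label sum
vector — so every observed word has a unit-length influence profile and
labels become comparable. Signed summation is the default (the influence is
"the change", which can be negative); magnitude summation is available
behind a flag. On generated corpora the faithfulness bar is concrete: the
top-1 knockout word for a label should be its planted keyword, and the test
suite asserts this for at least four of five labels.

## Embedding analyses

`embed_corpus()` extracts the classification embedding (projection output,
evaluation mode, canonical field order) for every case. `project_2d()` maps
embeddings to the plane with an exact O(n²) t-SNE — perplexity calibration
by binary search, early exaggeration, momentum gradient descent with
adaptive gains — written in R because no installed package provides t-SNE;
it is seeded and reproducible, suitable for the ≤1000-case corpora this
package targets, with PCA as the fast alternative. Cluster quality is
quantified two ways: mean silhouette of gold-label groups in the full
embedding space, and k-nearest-neighbour label agreement in the 2-D map
against a permuted-label baseline. `cooccurrence()` builds the symmetric
predicted-label co-occurrence matrix (diagonal = per-label totals) that a
chord diagram renders; the package emits the matrix and a static scatter,
not interactive graphics.

## The synthetic generator

`generate_corpus()` emulates the *structure* of an aspirate synopsis corpus
with fully known ground truth: 12 labels under a long-tailed prior (about
four labels expected below 20 cases in a 500-case sample, so rare-label
enrichment has something to do); directional co-occurrence pairs (e.g.
acute myeloid leukemia cases are often hypercellular); a "normal" label
mutually exclusive of abnormal labels except for iron deficiency; one unique
planted keyword per label written into a label-appropriate field, with
keyword presence *iff* label presence (strict mode); background text drawn
from per-field reporting vocabularies; and injected noise — signature
blocks, dictation disclaimers, reporting-system stamps, accession numbers —
matching the default cleaning patterns. The default hidden label
(plasma-cell neoplasm) is withheld from the oracle's initial sample and
co-occurs with several abnormal labels, so it can only enter the vocabulary
through review of cases sampled for other rare labels — the discovery
mechanism the loop is designed around. A `keyword_dropout` "hard mode"
weakens keyword determinism to study degradation; it is off everywhere the
suite asserts accuracy bars.

What passing tests on this corpus do **not** show: real synopses have no
single deterministic keyword per concept, their vocabulary is vastly larger,
negation and uncertainty matter, and inter-annotator disagreement exists.
The generator validates the *machinery* — sampling dynamics, discovery,
normalization contracts, directional comparisons — not clinical
performance.

## Numerical choices and degenerate inputs

* Decision threshold 0.5 (the natural BR default), configurable.
* Best-epoch ties → earliest epoch; top-word ties → lexicographic order.
* Scores saturate without overflow; the BCE is computed on the log scale.
* Empty texts encode to zero vectors; an all-below-threshold prediction is
  an abstention, flagged rather than forced.
* A validation size of zero in the MCCV splitter is an error; a saturated
  stage split (every case needed to cover labels) leaves validation empty
  with a warning.
* All randomness flows through explicit seeds, and library code restores
  the caller's RNG state.

Problem sizes in the shipped tests and the acceptance script — a 5-label
300-case sanity corpus (200 train / 100 validation), a 12-label 5000-case
pool for the active-learning runs, four seeds for the budget-matched
comparison, 1000 scored cases for the co-occurrence analysis — were chosen
as the smallest scales at which each phenomenon is stable and legible.

## Limitations

The built-in encoder is deliberately lightweight; swapping in a pretrained
transformer encoder (the intended production backend) changes embedding
quality but none of the surrounding machinery, which is written against the
encoder contract. Score calibration is out of scope — scores order labels
but are not probabilities. The active-learning strategy enriches rare
labels; uncertainty-based strategies (least confidence, margin, entropy)
are deliberately not implemented.
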