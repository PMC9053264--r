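# synoptic

Semantic labelling of semi-structured pathology synopses.

A bone marrow aspirate synopsis is an ordered list of `field: description`
pairs (cellularity, erythropoiesis, granulopoiesis, megakaryocytes,
lymphocytes, comment) that a hematopathologist reads into a handful of
diagnostic concepts — *normal*, *acute myeloid leukemia*, *hypercellular*,
and so on. One case may carry several such **semantic labels**, the labels
are heavily imbalanced, and the label set itself evolves as experts read
more cases. `synoptic` provides the full pipeline for learning this mapping
with minimal annotation:

- **Binary-relevance multi-label classifier.** Each synopsis is serialized
  to text, encoded by a feature-hashing encoder (unigrams + down-weighted
  bigrams, L2-normalized) with a trainable tanh projection, and scored by a
  sigmoid head: `S(x) = 1/(1 + e^{-x})` per label, trained with the
  per-label weighted binary cross-entropy
  `l_n = -w_n [y_n log σ(x_n) + (1-y_n) log(1-σ(x_n))]` under AdamW, with
  per-epoch snapshots and best-epoch selection by validation micro-F1.
- **Field-shuffle augmentation.** Field order carries no meaning, so
  training sees freshly permuted serializations each epoch and prediction
  takes the element-wise max of scores over several permuted views.
- **Rare-label active learning (CRL sampling).** Iteratively train, score
  the unlabeled pool, sample `threshold − count` cases per rare label from
  its predicted group (cap 100 per round, threshold decrement 5), have an
  oracle verify them, and merge — discovering new labels along the way —
  until every label has at least 20 labeled cases.
- **Adapted Monte Carlo cross-validation** guaranteeing each label
  `floor(min count × ratio)` validation cases.
- **Word-knockout interpretability**: per-word, per-label score deltas,
  summed over a labeled corpus by gold label and L2-normalized across
  labels; top-k word reports and heatmap export.
- **Embedding analyses**: classification-embedding extraction, seeded 2-D
  t-SNE/PCA projection, silhouette and kNN diagnostics, and predicted-label
  co-occurrence matrices for chord-diagram export.
- **Synthetic synopsis generator** with planted keywords, long-tailed label
  priors, co-occurrence structure, a "normal"-exclusivity rule, hidden
  labels, and injected reporting noise — plus a labelling oracle over it —
  so the whole pipeline is testable without protected clinical data.

## Worked example

```r
library(synoptic)

gen    <- generate_corpus(generator_config(n_cases = 300, seed = 1))
corpus <- clean_corpus(gen$corpus)               # strip signatures etc.
sp     <- mccv_split(corpus, 0.2, seed = 1)      # per-label validation floor
model  <- train_classifier(
  corpus[corpus$case_id %in% sp$train_ids, ],
  corpus[corpus$case_id %in% sp$validation_ids, ],
  cfg = lightweight_config(seed = 1))
model
#> <synoptic_model> 12 labels, embed dim 64, best epoch 9 (val micro-F1 0.927)
```

The fitted model keeps its per-epoch trace (`tidy(model)`, `autoplot(model)`)
and a one-row summary:

```r
glance(model)
#> # A tibble: 1 × 6
#>   best_epoch val_micro_f1 epochs n_labels embed_dim buckets
#>        <int>        <dbl>  <int>    <int>     <int>   <int>
#> 1          9        0.927     20       12        64    1024
```

Evaluation reports per-label and aggregate precision/recall/F1; micro-F1 is
computed from the summed confusion counts, so every (case, label) decision
counts equally:

```r
report <- evaluate_model(model,
  corpus[corpus$case_id %in% sp$validation_ids, ], augmented = FALSE)
report[report$level != "label", ]
#> # A tibble: 2 × 7
#>   label level precision recall    f1 support degenerate
#>   <chr> <chr>     <dbl>  <dbl> <dbl>   <dbl> <lgl>
#> 1 NA    micro     0.972  0.886 0.927      79 FALSE
#> 2 NA    macro     0.910  0.810 0.851      79 TRUE
```

Prediction uses augmented (max-over-views) scoring and thresholding at 0.5;
a case where nothing crosses the threshold is an explicit abstention:

```r
predict_labels(model, corpus[291:292, ])
#> # A tibble: 2 × 3
#>   case_id    labels    abstained
#>   <chr>      <list>    <lgl>
#> 1 case_00291 <chr [1]> FALSE     # hypercellular — matches gold
#> 2 case_00292 <chr [2]> FALSE     # normal + iron_deficiency — matches gold
```

Word knockout explains the fit: the top influence word for the acute
myeloid leukemia label is its planted marker token:

```r
tab <- influence_table(model, corpus[corpus$case_id %in% sp$train_ids, ])
top_k_words(tab, "acute_myeloid_leukemia", 5)
#> [1] "myeloblasts"  "forms"  "review"  "granulocytic"  "cytometry"
```

For the full loop — seeding 50 labeled cases, enriching rare labels against
an oracle until every label has 20 cases, discovering hidden labels — see
`run_active_learning()`; a file-based oracle (`file_oracle()`) supports
human-in-the-loop deployments, and `inst/cli/synoptic.R` wraps generate /
train / predict / evaluate / al-run for shell use.

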