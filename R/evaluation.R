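# Per-label and micro-averaged precision/recall/F1 under binary relevance,
# and the learning-curve experiment.

#' Per-label confusion counts
#'
#' Treats every label as an independent binary decision (binary relevance)
#' and tallies true/false positives/negatives per label over the evaluated
#' cases. Predictions and gold standards are matched by `case_id`.
#'
#' @param pred Tibble with `case_id` and `labels` list-column of predicted
#'   label sets (e.g. from [predict_labels()]).
#' @param gold Tibble with `case_id` and `labels` list-column of gold label
#'   sets, or a labeled corpus.
#' @param vocab A [label_vocabulary()] or character vector; labels outside
#'   it are an error.
#' @return Tibble with `label`, `tp`, `fp`, `fn`, `tn`; per label the four
#'   counts sum to the number of cases.
#' @export
confusion_counts <- function(pred, gold, vocab) {
  labs <- vocab_labels(vocab)
  pred <- as_tibble(pred)
  gold <- as_tibble(gold)
  if (!setequal(pred$case_id, gold$case_id) ||
      nrow(pred) != nrow(gold)) {
    abort("pred and gold must cover the same case ids")
  }
  gold <- gold[match(pred$case_id, gold$case_id), ]
  unknown <- setdiff(unique(c(unlist(pred$labels), unlist(gold$labels))),
                     labs)
  if (length(unknown)) {
    abort(paste0("labels not in vocabulary: ", paste(unknown, collapse = ", ")))
  }
  P <- targets_matrix(pred$labels, labs) > 0
  G <- targets_matrix(gold$labels, labs) > 0
  tibble(label = labs,
         tp = unname(colSums(P & G)), fp = unname(colSums(P & !G)),
         fn = unname(colSums(!P & G)), tn = unname(colSums(!P & !G)))
}

safe_div <- function(num, den) ifelse(den == 0, 0, num / den)

#' Precision, recall and F1 from confusion counts
#'
#' Per label: `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`. The `micro` row recomputes all three from the summed
#' counts (micro-F1 is the harmonic mean of micro-precision and
#' micro-recall); the `macro` row is the unweighted mean of the per-label
#' metrics, reported for diagnostics only. A 0/0 quotient is reported as 0
#' and flagged `degenerate`.
#'
#' @param counts Output of [confusion_counts()].
#' @return Tibble with `label`, `level` (`"label"`, `"micro"`, `"macro"`),
#'   `precision`, `recall`, `f1`, `support`, `degenerate`.
#' @export
eval_metrics <- function(counts) {
  stopifnot(all(c("label", "tp", "fp", "fn") %in% names(counts)))
  per <- mutate(counts,
    level = "label",
    support = .data$tp + .data$fn,
    precision = safe_div(.data$tp, .data$tp + .data$fp),
    recall = safe_div(.data$tp, .data$tp + .data$fn),
    f1 = safe_div(2 * .data$precision * .data$recall,
                  .data$precision + .data$recall),
    degenerate = (.data$tp + .data$fp == 0) | (.data$tp + .data$fn == 0) |
      (.data$precision + .data$recall == 0))
  tps <- sum(counts$tp); fps <- sum(counts$fp); fns <- sum(counts$fn)
  mp <- safe_div(tps, tps + fps)
  mr <- safe_div(tps, tps + fns)
  micro <- tibble(label = NA_character_, level = "micro",
                  support = tps + fns,
                  precision = mp, recall = mr,
                  f1 = safe_div(2 * mp * mr, mp + mr),
                  degenerate = (tps + fps == 0) | (tps + fns == 0) |
                    (mp + mr == 0))
  macro <- tibble(label = NA_character_, level = "macro",
                  support = tps + fns,
                  precision = mean(per$precision),
                  recall = mean(per$recall),
                  f1 = mean(per$f1), degenerate = any(per$degenerate))
  bind_rows(select(per, "label", "level", "precision", "recall", "f1",
                   "support", "degenerate"),
            micro, macro)
}

#' Micro-average F1 between predicted and gold label sets
#'
#' @inheritParams confusion_counts
#' @return A single number in `[0, 1]`.
#' @export
micro_f1 <- function(pred, gold, vocab) {
  m <- eval_metrics(confusion_counts(pred, gold, vocab))
  unname(m$f1[m$level == "micro"])
}

gold_tibble <- function(corpus) {
  corpus <- labeled_cases(as_corpus(corpus))
  tibble(case_id = corpus$case_id, labels = corpus$labels)
}

#' Evaluate a fitted model on a labeled corpus
#'
#' @param model A `synoptic_model`.
#' @param corpus Labeled corpus tibble.
#' @param augmented,n_views,seed Prediction controls (see
#'   [predict_labels()]).
#' @return The [eval_metrics()] tibble.
#' @export
evaluate_model <- function(model, corpus, augmented = TRUE, n_views = NULL,
                           seed = 1L) {
  pred <- predict_labels(model, corpus, augmented, n_views, seed)
  vocab <- label_vocabulary(unique(c(vocab_labels(model$vocab),
                                     unlist(corpus$labels))))
  eval_metrics(confusion_counts(pred, gold_tibble(corpus), vocab))
}

#' Learning curve over nested training prefixes
#'
#' Trains on nested prefixes of the training corpus (sizes `batch_size`,
#' `2 * batch_size`, ...) against one fixed benchmark validation set,
#' repeating over seeds (each seed reshuffles the prefix order and re-seeds
#' training), and reports the mean validation micro-F1 and its standard
#' error per labeling budget.
#'
#' @param train_corpus Labeled corpus supplying the nested prefixes.
#' @param val_corpus Fixed labeled benchmark validation corpus.
#' @param cfg A [train_config()].
#' @param batch_size Budget step (default 50).
#' @param seeds Integer seeds, one run per seed.
#' @param vocab Optional vocabulary (defaults to all labels seen).
#' @return Tibble with `n_train`, `mean_micro_f1`, `sem`, `n_runs`; the
#'   per-run values are attached as attribute `runs`.
#' @export
learning_curve <- function(train_corpus, val_corpus, cfg = train_config(),
                           batch_size = 50L, seeds = 1:4, vocab = NULL) {
  train_corpus <- labeled_cases(as_corpus(train_corpus))
  val_corpus <- labeled_cases(as_corpus(val_corpus))
  n <- nrow(train_corpus)
  if (batch_size > n) abort("batch_size exceeds the training pool")
  budgets <- seq(batch_size, n, by = batch_size)
  vocab <- vocab %||% label_vocabulary(
    unique(c(unlist(train_corpus$labels), unlist(val_corpus$labels))))
  gold <- gold_tibble(val_corpus)
  runs <- list()
  for (s in seeds) {
    ord <- with_seed(s, sample.int(n))
    for (b in budgets) {
      sub <- train_corpus[ord[seq_len(b)], ]
      cfg_s <- cfg
      cfg_s$seed <- as.integer((cfg$seed + s) %% 2147483647)
      model <- suppressWarnings(train_classifier(
        sub, val_corpus, vocab, cfg_s))
      pred <- predict_labels(model, val_corpus, augmented = FALSE)
      runs[[length(runs) + 1L]] <- tibble(
        seed = s, n_train = b, micro_f1 = micro_f1(pred, gold, vocab))
    }
  }
  runs <- bind_rows(runs)
  out <- runs |>
    group_by(.data$n_train) |>
    summarise(mean_micro_f1 = mean(.data$micro_f1),
              sem = stats::sd(.data$micro_f1) / sqrt(n()),
              n_runs = n(), .groups = "drop")
  attr(out, "runs") <- runs
  out
}
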