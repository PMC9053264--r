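pred_gold_pair <- function() {
  vocab <- label_vocabulary(c("A", "B", "C"))
  gold <- tibble::tibble(case_id = c("1", "2", "3", "4"),
                         labels = list("A", c("A", "B"), "C", "B"))
  pred <- tibble::tibble(case_id = c("1", "2", "3", "4"),
                         labels = list("B", c("A", "B"), "C", "B"))
  list(vocab = vocab, gold = gold, pred = pred)
}

test_that("confusion counts follow the binary-relevance tally", {
  p <- pred_gold_pair()
  # perfect prediction: no false hits or misses
  cc <- confusion_counts(p$gold, p$gold, p$vocab)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  expect_true(all(cc$tp + cc$fp + cc$fn + cc$tn == 4))
  # single disagreement: gold {A}, pred {B}
  cc2 <- confusion_counts(p$pred[1, ], p$gold[1, ], p$vocab)
  expect_identical(cc2$fn[cc2$label == "A"], 1)
  expect_identical(cc2$fp[cc2$label == "B"], 1)
  # the 4-case table equals an exhaustive manual tally
  cc3 <- confusion_counts(p$pred, p$gold, p$vocab)
  for (lab in vocab_labels(p$vocab)) {
    tp <- fp <- fn <- tn <- 0
    for (i in 1:4) {
      ing <- lab %in% p$gold$labels[[i]]
      inp <- lab %in% p$pred$labels[[i]]
      if (inp && ing) tp <- tp + 1
      if (inp && !ing) fp <- fp + 1
      if (!inp && ing) fn <- fn + 1
      if (!inp && !ing) tn <- tn + 1
    }
    row <- cc3[cc3$label == lab, ]
    expect_identical(c(row$tp, row$fp, row$fn, row$tn), c(tp, fp, fn, tn))
  }
  expect_error(confusion_counts(p$pred[1:2, ], p$gold, p$vocab), "same case ids")
})

test_that("metrics reproduce the precision/recall/F1 formulas with the 0/0 convention", {
  p <- pred_gold_pair()
  perfect <- eval_metrics(confusion_counts(p$gold, p$gold, p$vocab))
  expect_true(all(perfect$precision == 1 & perfect$recall == 1 &
                    perfect$f1 == 1))
  # micro P = R = F1 = 2/3 from TP_sum 2, FP_sum 1, FN_sum 1
  counts <- tibble::tibble(label = c("x", "y"), tp = c(2, 0), fp = c(1, 0),
                           fn = c(1, 0), tn = c(0, 3))
  m <- eval_metrics(counts)
  micro <- m[m$level == "micro", ]
  expect_equal(c(micro$precision, micro$recall, micro$f1), rep(2 / 3, 3),
               tolerance = 1e-12)
  # degenerate label: no predictions, positives missed
  deg <- tibble::tibble(label = "z", tp = 0, fp = 0, fn = 3, tn = 7)
  md <- eval_metrics(deg)
  lab_row <- md[md$level == "label", ]
  expect_identical(lab_row$precision, 0)
  expect_identical(lab_row$recall, 0)
  expect_true(lab_row$degenerate)
})

test_that("metrics agree with a brute-force per-(case,label) oracle on random inputs", {
  brute_micro <- function(pred, gold, labs) {
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      for (lab in labs) {
        ing <- lab %in% gold[[i]]
        inp <- lab %in% pred[[i]]
        tp <- tp + (inp && ing); fp <- fp + (inp && !ing)
        fn <- fn + (!inp && ing)
      }
    }
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  set.seed(19)
  for (rep in 1:30) {
    labs <- paste0("l", seq_len(sample(2:6, 1)))
    n <- sample(3:12, 1)
    draw <- function() lapply(seq_len(n), function(i) {
      sample(labs, sample(0:length(labs), 1))
    })
    gold <- draw(); pred <- draw()
    ids <- as.character(seq_len(n))
    got <- micro_f1(tibble::tibble(case_id = ids, labels = pred),
                    tibble::tibble(case_id = ids, labels = gold), labs)
    expect_equal(got, brute_micro(pred, gold, labs), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to case order", {
  p <- pred_gold_pair()
  base <- eval_metrics(confusion_counts(p$pred, p$gold, p$vocab))
  perm <- c(3, 1, 4, 2)
  flip <- eval_metrics(confusion_counts(p$pred[perm, ], p$gold, p$vocab))
  expect_equal(base, flip, tolerance = 1e-15)
})

test_that("micro-F1 lies between per-label extremes when nothing is degenerate", {
  p <- pred_gold_pair()
  m <- eval_metrics(confusion_counts(p$pred, p$gold, p$vocab))
  per <- m[m$level == "label" & !m$degenerate, ]
  micro <- m$f1[m$level == "micro"]
  expect_gte(micro, min(per$f1))
  expect_lte(micro, max(per$f1))
})

test_that("the learning curve rises with training budget on the sanity corpus", {
  fit <- sanity_fit()
  curve <- suppressWarnings(learning_curve(
    fit$train, fit$validation,
    cfg = lightweight_config(epochs = 8L, batch_size = 8L),
    batch_size = 100L, seeds = 1:2))
  expect_named(curve, c("n_train", "mean_micro_f1", "sem", "n_runs"))
  expect_identical(curve$n_train, c(100L, 200L))
  expect_gte(curve$mean_micro_f1[2], curve$mean_micro_f1[1] - 0.02)
  runs <- attr(curve, "runs")
  expect_identical(nrow(runs), 4L)
  # single batch, single seed: a one-row table
  one <- suppressWarnings(learning_curve(
    fit$train[1:60, ], fit$validation, cfg = quick_config(),
    batch_size = 60L, seeds = 1))
  expect_identical(nrow(one), 1L)
  expect_error(learning_curve(fit$train[1:10, ], fit$validation,
                              batch_size = 50L), "exceeds")
})
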