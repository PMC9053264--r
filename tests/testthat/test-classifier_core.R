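test_that("sigmoid matches the closed form and its symmetry identities", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(10), 0.999954602131298, tolerance = 1e-12)
  xs <- seq(-30, 30, length.out = 101)
  expect_equal(sigmoid(-xs), 1 - sigmoid(xs), tolerance = 1e-12)
  expect_true(all(diff(sigmoid(xs)) > 0))
  expect_equal(sigmoid(800), 1)    # saturates without overflow
  expect_equal(sigmoid(-800), 0)
})

test_that("bce_loss matches closed-form points and a brute-force oracle", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(20, 1), 1e-8)
  # batch of identical items equals the single-item loss
  one <- bce_loss(matrix(c(0.3, -1.2), 1), matrix(c(1, 0), 1))
  rep5 <- bce_loss(matrix(c(0.3, -1.2), 5, 2, byrow = TRUE),
                   matrix(c(1, 0), 5, 2, byrow = TRUE))
  expect_equal(one, rep5, tolerance = 1e-12)
  # independent brute-force summation over random small batches
  brute <- function(x, y, w) {
    tot <- 0
    for (i in seq_len(nrow(x))) {
      item <- 0
      for (j in seq_len(ncol(x))) {
        s <- 1 / (1 + exp(-x[i, j]))
        item <- item - w[j] * (y[i, j] * log(s) + (1 - y[i, j]) * log(1 - s))
      }
      tot <- tot + item / ncol(x)
    }
    tot / nrow(x)
  }
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(1:6, 1); L <- sample(1:5, 1)
    x <- matrix(rnorm(n * L, sd = 3), n, L)
    y <- matrix(rbinom(n * L, 1, 0.4), n, L)
    w <- runif(L, 0.5, 2)
    expect_equal(bce_loss(x, y, w), brute(x, y, w), tolerance = 1e-9)
  }
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "same shape")
})

test_that("encode_text is deterministic, pads, and truncates at the maximum", {
  spec <- encoder_spec(max_tokens = 8)
  e <- encode_text("", spec)
  expect_identical(e$token_ids[1], 1L)
  expect_identical(sum(e$attention_mask), 1L)
  expect_length(e$token_ids, 9L)
  t1 <- encode_text("erythroid series normoblastic", spec)
  t2 <- encode_text("erythroid series normoblastic", spec)
  expect_identical(t1, t2)
  long <- paste(rep("token", 30), collapse = " ")
  expect_warning(e3 <- encode_text(long, spec), "truncated")
  expect_identical(sum(e3$attention_mask), 9L)
})

test_that("training is seed-deterministic with best-epoch selection dominating the trace", {
  gen <- generate_corpus(sanity_generator_config(n_cases = 80, seed = 21))
  corpus <- clean_corpus(gen$corpus)
  tr <- corpus[1:60, ]; va <- corpus[61:80, ]
  m1 <- suppressWarnings(train_classifier(tr, va, cfg = quick_config(seed = 3)))
  m2 <- suppressWarnings(train_classifier(tr, va, cfg = quick_config(seed = 3)))
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$W2, m2$W2)
  best <- m1$trace$val_micro_f1[m1$best_epoch]
  expect_true(all(best >= m1$trace$val_micro_f1))
  # earliest epoch wins ties
  expect_identical(m1$best_epoch,
                   which(m1$trace$val_micro_f1 == best)[1])
  # single-epoch training returns the only snapshot
  m3 <- suppressWarnings(train_classifier(tr, va,
                                          cfg = quick_config(epochs = 1L)))
  expect_identical(m3$best_epoch, 1L)
})

test_that("train_classifier rejects degenerate inputs", {
  corpus <- toy_corpus()
  expect_error(train_classifier(corpus[0, ], corpus, cfg = quick_config()),
               "non-empty")
  vocab <- label_vocabulary(c("normal", "iron"))
  expect_error(
    suppressWarnings(train_classifier(corpus[c(2, 4), ], corpus[1, ], vocab,
                                      quick_config())),
    "absent from vocabulary")
})

test_that("predicted scores are the sigmoid of the head logits", {
  fit <- sanity_fit()
  model <- fit$model
  X <- synoptic:::encode_corpus(fit$validation, model$cfg$encoder)
  Z <- tanh(sweep(X %*% model$W1, 2, model$b1, `+`))
  logits <- sweep(Z %*% model$W2, 2, model$b2, `+`)
  S <- predict_scores(model, fit$validation, augmented = FALSE)
  expect_equal(unname(S), unname(sigmoid(logits)), tolerance = 1e-12)
  expect_true(all(S > 0 & S < 1))
})

test_that("thresholding turns scores into label sets, with abstention flagged", {
  fit <- sanity_fit()
  S <- predict_scores(fit$model, fit$validation, augmented = FALSE)
  labs <- vocab_labels(fit$model$vocab)
  pl <- predict_labels(fit$model, fit$validation, augmented = FALSE)
  for (i in c(1, 7, 20)) {
    expect_identical(pl$labels[[i]], labs[S[i, ] >= 0.5])
  }
  expect_identical(pl$abstained, lengths(pl$labels) == 0L)
  # manual thresholding example
  fake <- fit$model
  long <- predict(fit$model, fit$validation[1:2, ], augmented = FALSE)
  expect_identical(long$predicted, long$score >= 0.5)
})

test_that("planted keywords drive the trained model's validation predictions", {
  fit <- sanity_fit()
  expect_gte(glance(fit$model)$val_micro_f1, 0.9)
  kw <- fit$gen$truth$keywords
  pl <- predict_labels(fit$model, fit$validation, augmented = FALSE)
  # the unique keyword of a label places that label in the predicted set
  # for the overwhelming majority of validation cases
  hit <- 0; tot <- 0
  for (i in seq_len(nrow(fit$validation))) {
    toks <- unlist(synoptic:::tokenize_words(unname(fit$validation$fields[[i]])))
    for (lab in names(kw)) {
      if (kw[[lab]] %in% toks) {
        tot <- tot + 1
        hit <- hit + (lab %in% pl$labels[[i]])
      }
    }
  }
  expect_gte(hit / tot, 0.9)
})

test_that("embeddings are deterministic, text-pure functions of the configured width", {
  fit <- sanity_fit()
  e1 <- extract_embedding(fit$model, fit$validation)
  e2 <- extract_embedding(fit$model, fit$validation)
  expect_identical(e1, e2)
  expect_identical(ncol(e1), fit$model$cfg$encoder$embed_dim)
  twin <- corpus_tbl(c("t1", "t2"),
                     list(fit$validation$fields[[1]],
                          fit$validation$fields[[1]]))
  et <- extract_embedding(fit$model, twin)
  expect_equal(et[1, ], et[2, ], tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("a model round-trips through the plain-text artifact directory", {
  fit <- sanity_fit()
  dir <- withr::local_tempdir()
  save_model(fit$model, dir)
  expect_true(all(file.exists(file.path(dir,
    c("config.json", "vocabulary.json", "W1.tsv", "trace.csv")))))
  back <- load_model(dir)
  S1 <- predict_scores(fit$model, fit$validation[1:5, ], augmented = FALSE)
  S2 <- predict_scores(back, fit$validation[1:5, ], augmented = FALSE)
  expect_equal(S1, S2, tolerance = 1e-8)
  expect_identical(vocab_labels(back$vocab), vocab_labels(fit$model$vocab))
})

test_that("tidy and glance expose the metric trace and the selected epoch", {
  fit <- sanity_fit()
  tr <- tidy(fit$model)
  expect_named(tr, c("epoch", "train_loss", "val_micro_f1"))
  expect_identical(nrow(tr), as.integer(fit$model$cfg$epochs))
  g <- glance(fit$model)
  expect_identical(g$val_micro_f1, tr$val_micro_f1[g$best_epoch])
})
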