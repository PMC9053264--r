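# Binary-relevance classifier: sigmoid head over the feature-hashing encoder
# with a trainable tanh projection, trained by decoupled-weight-decay Adam
# (AdamW) on a per-label binary cross-entropy, with per-epoch field-shuffle
# augmentation and best-epoch selection by validation micro-F1.

#' Logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, the map from a label's logit to its
#' prediction score. Strictly increasing, `sigmoid(0) = 0.5`, and
#' `sigmoid(-x) = 1 - sigmoid(x)`; saturates at the extremes without
#' overflow.
#'
#' @param x Numeric vector/matrix of logits.
#' @return Values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Weighted binary cross-entropy loss
#'
#' For a batch of logit rows `x` and 0/1 target rows `y`, the per-item loss
#' is the mean over labels of
#' `-w_n * (y * log(sigmoid(x)) + (1 - y) * log(1 - sigmoid(x)))`,
#' and the batch loss is the mean over items. Computed on the log scale for
#' numerical stability; nonnegative, and zero only in the saturation limit.
#'
#' @param logits Numeric matrix (items x labels) or vector.
#' @param targets 0/1 matrix or vector, same shape.
#' @param weights Per-label positive weights `w_n`; default all 1.
#' @return A single nonnegative number.
#' @export
bce_loss <- function(logits, targets, weights = NULL) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1)
  if (!all(dim(logits) == dim(targets))) {
    abort("logits and targets must have the same shape")
  }
  L <- ncol(logits)
  w <- if (is.null(weights)) rep(1, L) else as.numeric(weights)
  if (length(w) != L) abort("weights length must equal the label count")
  # log(sigmoid(x)) = -log1p(exp(-x)), computed stably on both tails
  log_sig <- ifelse(logits >= 0, -log1p(exp(-logits)),
                    logits - log1p(exp(logits)))
  log_1msig <- ifelse(logits >= 0, -logits - log1p(exp(-logits)),
                      -log1p(exp(logits)))
  per <- -(targets * log_sig + (1 - targets) * log_1msig)
  per <- sweep(per, 2, w, `*`)
  mean(rowMeans(per))
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with learning rate
#' 1e-3 and weight decay 1e-2, 10 epochs, dropout 0.5 on the classification
#' head input, per-label loss weights all 1, and a 0.5 decision threshold for
#' turning scores into labels.
#'
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay (applied to weight matrices,
#'   not biases).
#' @param epochs Training epochs; one snapshot is taken per epoch and the
#'   best validation micro-F1 snapshot is returned (earliest epoch on ties).
#' @param dropout Dropout rate on the classification embedding during
#'   training, in `[0, 1)`.
#' @param batch_size Minibatch size.
#' @param label_weights Optional per-label loss weights `w_n`.
#' @param decision_threshold Score threshold for label assignment, in (0, 1).
#' @param seed Integer seed controlling initialization, shuffling, dropout
#'   and augmentation; runs are reproducible given the seed.
#' @param encoder An [encoder_spec()].
#' @param train_views Field-order views per case per epoch (training
#'   augmentation; resampled every epoch).
#' @param predict_views Views used by augmented prediction.
#' @param augment Use field-shuffle augmentation during training.
#' @param augmented_selection Use augmented prediction when computing the
#'   per-epoch validation micro-F1 (off by default; both paths are exposed).
#' @param input_dropout Dropout rate on the hashed input features during
#'   training (regularizes against memorizing case-specific token
#'   combinations); 0 by default, raised by [lightweight_config()].
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-2,
                         epochs = 10L, dropout = 0.5, batch_size = 16L,
                         label_weights = NULL, decision_threshold = 0.5,
                         seed = 42L, encoder = encoder_spec(),
                         train_views = 3L, predict_views = 5L,
                         augment = TRUE, augmented_selection = FALSE,
                         input_dropout = 0) {
  stopifnot(learning_rate > 0, weight_decay >= 0, is_count(epochs),
            dropout >= 0, dropout < 1, is_count(batch_size),
            decision_threshold > 0, decision_threshold < 1,
            inherits(encoder, "encoder_spec"),
            is_count(train_views), is_count(predict_views),
            input_dropout >= 0, input_dropout < 1)
  structure(list(
    learning_rate = learning_rate, weight_decay = weight_decay,
    epochs = as.integer(epochs), dropout = dropout,
    batch_size = as.integer(batch_size), label_weights = label_weights,
    decision_threshold = decision_threshold, seed = as.integer(seed),
    encoder = encoder, train_views = as.integer(train_views),
    predict_views = as.integer(predict_views), augment = isTRUE(augment),
    augmented_selection = isTRUE(augmented_selection),
    input_dropout = input_dropout),
    class = "train_config")
}

#' Training preset for the feature-hashing backend
#'
#' [train_config()]'s defaults mirror the fine-tuning recipe appropriate for
#' a large pretrained encoder, where small steps over few epochs suffice
#' because the representation is already trained. The hashing backend trains
#' its projection and head from random initialization, which needs a larger
#' learning rate, more optimization steps (smaller batches, more epochs) and
#' input-feature dropout to generalize instead of memorize. This preset is
#' the recommended configuration whenever the built-in encoder is used.
#'
#' @param ... Overrides passed on to [train_config()].
#' @return A `train_config`.
#' @export
lightweight_config <- function(...) {
  defaults <- list(learning_rate = 1e-2, batch_size = 4L, epochs = 20L,
                   input_dropout = 0.15)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Binary target matrix for a label vocabulary
#'
#' @param labels_list List of character label vectors, one per case.
#' @param vocab A [label_vocabulary()] or character vector.
#' @return 0/1 matrix, cases x labels.
#' @export
targets_matrix <- function(labels_list, vocab) {
  labs <- vocab_labels(vocab)
  out <- matrix(0L, length(labels_list), length(labs),
                dimnames = list(NULL, labs))
  for (i in seq_along(labels_list)) {
    hit <- match(labels_list[[i]], labs)
    if (anyNA(hit)) {
      abort(paste0("label not in vocabulary: ",
                   paste(labels_list[[i]][is.na(hit)], collapse = ", ")))
    }
    out[i, hit] <- 1L
  }
  out
}

# micro-F1 from boolean prediction/gold matrices (degenerate 0/0 -> 0)
micro_f1_mat <- function(pred, gold) {
  tp <- sum(pred & gold)
  fp <- sum(pred & !gold)
  fn <- sum(!pred & gold)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

adamw_new <- function(p) list(m = p * 0, v = p * 0)

adamw_step <- function(p, g, st, lr, wd, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
  list(p = p, st = st)
}

# One serialized view per (case, view); resamples permutations. Uses the
# current RNG stream.
shuffle_views <- function(fields_list, n_views, warn_replace = FALSE) {
  texts <- character(0)
  idx <- integer(0)
  for (i in seq_along(fields_list)) {
    f <- fields_list[[i]]
    perms <- sample_permutations(length(f), n_views, warn_replace)
    texts <- c(texts, vapply(seq_len(nrow(perms)), function(v) {
      serialize_synopsis(f, perms[v, ])
    }, character(1)))
    idx <- c(idx, rep(i, n_views))
  }
  list(texts = texts, case = idx)
}

#' Train the binary-relevance classifier
#'
#' Runs `cfg$epochs` epochs of AdamW on the weighted binary cross-entropy
#' over all labels. Each epoch the training texts are re-serialized under
#' `cfg$train_views` freshly sampled field orders (field-shuffle
#' augmentation), the model is snapshotted, and the validation micro-F1 is
#' recorded; the returned model is the snapshot with the highest validation
#' micro-F1 (earliest epoch on ties). Deterministic given `cfg$seed`.
#'
#' @param train,validation Labeled corpus tibbles (both non-empty).
#' @param vocab Optional [label_vocabulary()]; defaults to the labels
#'   observed in `train` and `validation`. Validation labels outside the
#'   vocabulary are an error.
#' @param cfg A [train_config()].
#' @return A fitted `synoptic_model` with the per-epoch metric trace.
#' @export
train_classifier <- function(train, validation, vocab = NULL,
                             cfg = train_config()) {
  train <- labeled_cases(as_corpus(train))
  validation <- labeled_cases(as_corpus(validation))
  if (!nrow(train) || !nrow(validation)) {
    abort("both training and validation splits must be non-empty")
  }
  if (is.null(vocab)) {
    vocab <- label_vocabulary(unique(c(unlist(train$labels),
                                       unlist(validation$labels))))
  }
  labs <- vocab_labels(vocab)
  extra <- setdiff(unique(unlist(validation$labels)), labs)
  if (length(extra)) {
    abort(paste0("validation labels absent from vocabulary: ",
                 paste(extra, collapse = ", ")))
  }
  missing_train <- setdiff(labs, unique(unlist(train$labels)))
  if (length(missing_train)) {
    warn(paste0("vocabulary labels with no training case: ",
                paste(missing_train, collapse = ", ")))
  }

  spec <- cfg$encoder
  H <- spec$buckets; d <- spec$embed_dim; L <- length(labs)
  w <- if (is.null(cfg$label_weights)) rep(1, L) else cfg$label_weights
  if (length(w) != L) abort("label_weights length must equal |vocabulary|")

  Y <- targets_matrix(train$labels, labs)
  Yv <- targets_matrix(validation$labels, labs) > 0
  Xv <- encode_corpus(validation, spec)
  Xtr_canon <- if (cfg$augment) NULL else encode_corpus(train, spec)

  with_seed(cfg$seed, {
    W1 <- matrix(rnorm(H * d, sd = sqrt(2 / (H + d))), H, d)
    b1 <- rep(0, d)
    W2 <- matrix(rnorm(d * L, sd = sqrt(2 / (d + L))), d, L)
    # head bias starts at the per-label training prior logit
    b2 <- unname(stats::qlogis(clamp(colMeans(Y), 1e-3, 1 - 1e-3)))
    st <- list(W1 = adamw_new(W1), b1 = adamw_new(b1),
               W2 = adamw_new(W2), b2 = adamw_new(b2))
    step <- 0L
    trace <- vector("list", cfg$epochs)
    best <- list(f1 = -Inf, epoch = NA_integer_)

    for (epoch in seq_len(cfg$epochs)) {
      if (cfg$augment) {
        views <- shuffle_views(train$fields, cfg$train_views)
        X <- encode_features(views$texts, spec)
        Yb <- Y[views$case, , drop = FALSE]
      } else {
        X <- Xtr_canon
        Yb <- Y
      }
      n <- nrow(X)
      ord <- sample.int(n)
      total_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        xb <- X[b, , drop = FALSE]
        yb <- Yb[b, , drop = FALSE]
        nb <- length(b)
        if (cfg$input_dropout > 0) {
          xb <- xb * matrix(
            (runif(nb * H) >= cfg$input_dropout) / (1 - cfg$input_dropout),
            nb, H)
        }
        Z <- tanh(sweep(xb %*% W1, 2, b1, `+`))
        if (cfg$dropout > 0) {
          mask <- matrix((runif(nb * d) >= cfg$dropout) / (1 - cfg$dropout),
                         nb, d)
          Zd <- Z * mask
        } else {
          Zd <- Z
        }
        logits <- sweep(Zd %*% W2, 2, b2, `+`)
        total_loss <- total_loss + nb * bce_loss(logits, yb, w)
        dlogit <- sweep(sigmoid(logits) - yb, 2, w, `*`) / (L * nb)
        gW2 <- crossprod(Zd, dlogit)
        gb2 <- colSums(dlogit)
        dZd <- dlogit %*% t(W2)
        dZ <- if (cfg$dropout > 0) dZd * mask else dZd
        dpre <- dZ * (1 - Z * Z)
        gW1 <- crossprod(xb, dpre)
        gb1 <- colSums(dpre)
        step <- step + 1L
        up <- adamw_step(W1, gW1, st$W1, cfg$learning_rate,
                         cfg$weight_decay, step)
        W1 <- up$p; st$W1 <- up$st
        up <- adamw_step(b1, gb1, st$b1, cfg$learning_rate, 0, step)
        b1 <- up$p; st$b1 <- up$st
        up <- adamw_step(W2, gW2, st$W2, cfg$learning_rate,
                         cfg$weight_decay, step)
        W2 <- up$p; st$W2 <- up$st
        up <- adamw_step(b2, gb2, st$b2, cfg$learning_rate, 0, step)
        b2 <- up$p; st$b2 <- up$st
      }

      snap <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      val_scores <- if (cfg$augmented_selection) {
        score_matrix_params(snap, validation, spec, augmented = TRUE,
                            n_views = cfg$predict_views, seed = cfg$seed)
      } else {
        forward_scores(snap, Xv)
      }
      val_f1 <- micro_f1_mat(val_scores >= cfg$decision_threshold, Yv)
      trace[[epoch]] <- tibble(epoch = epoch,
                               train_loss = total_loss / n,
                               val_micro_f1 = val_f1)
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, epoch = epoch, params = snap)
      }
    }
  })

  structure(list(
    W1 = best$params$W1, b1 = best$params$b1,
    W2 = best$params$W2, b2 = best$params$b2,
    vocab = if (inherits(vocab, "label_vocabulary")) vocab
            else label_vocabulary(labs),
    cfg = cfg, trace = bind_rows(trace), best_epoch = best$epoch),
    class = "synoptic_model")
}

forward_scores <- function(params, X) {
  Z <- tanh(sweep(X %*% params$W1, 2, params$b1, `+`))
  sigmoid(sweep(Z %*% params$W2, 2, params$b2, `+`))
}

forward_embedding <- function(params, X) {
  tanh(sweep(X %*% params$W1, 2, params$b1, `+`))
}

score_matrix_params <- function(params, corpus, spec, augmented, n_views,
                                seed) {
  corpus <- as_corpus(corpus)
  if (!nrow(corpus)) return(matrix(0, 0, ncol(params$W2)))
  if (!augmented || n_views <= 1L) {
    return(forward_scores(params, encode_corpus(corpus, spec)))
  }
  with_seed(seed, {
    views <- shuffle_views(corpus$fields, n_views)
  })
  S <- forward_scores(params, encode_features(views$texts, spec))
  out <- matrix(-Inf, nrow(corpus), ncol(S))
  for (r in seq_len(nrow(S))) {
    i <- views$case[r]
    out[i, ] <- pmax(out[i, ], S[r, ])
  }
  out
}

#' Per-label prediction scores for a corpus
#'
#' @param model A fitted `synoptic_model`.
#' @param corpus A corpus tibble.
#' @param augmented Use field-shuffle augmented prediction (element-wise max
#'   of the scores over `n_views` permuted serializations).
#' @param n_views Number of views; defaults to the model's
#'   `predict_views`.
#' @param seed Seed for the view permutations.
#' @return Numeric matrix, cases x labels, scores in (0, 1), with
#'   `case_id` rownames.
#' @export
predict_scores <- function(model, corpus, augmented = TRUE, n_views = NULL,
                           seed = 1L) {
  stopifnot(inherits(model, "synoptic_model"))
  corpus <- as_corpus(corpus)
  n_views <- n_views %||% model$cfg$predict_views
  S <- score_matrix_params(model, corpus, model$cfg$encoder, augmented,
                           n_views, seed)
  dimnames(S) <- list(corpus$case_id, vocab_labels(model$vocab))
  S
}

#' Predict semantic labels for new synopses
#'
#' Scores every vocabulary label with the sigmoid head (augmented prediction
#' by default) and marks labels at or above the decision threshold as
#' predicted. A case where every score is below the threshold is an
#' abstention (`abstained` in [predict_labels()]).
#'
#' @param object A fitted `synoptic_model`.
#' @param newdata A corpus tibble.
#' @param augmented Use augmented prediction.
#' @param n_views,seed View sampling controls.
#' @param threshold Decision threshold; defaults to the training config.
#' @param ... Unused.
#' @return A long tibble with `case_id`, `label`, `score`, `predicted`.
#' @export
predict.synoptic_model <- function(object, newdata, augmented = TRUE,
                                   n_views = NULL, seed = 1L,
                                   threshold = NULL, ...) {
  threshold <- threshold %||% object$cfg$decision_threshold
  S <- predict_scores(object, newdata, augmented, n_views, seed)
  out <- as_tibble(as.data.frame.table(S, stringsAsFactors = FALSE))
  names(out) <- c("case_id", "label", "score")
  out$predicted <- out$score >= threshold
  arrange(out, match(.data$case_id, rownames(S)))
}

#' Predicted label sets per case
#'
#' @inheritParams predict.synoptic_model
#' @param model A fitted `synoptic_model`.
#' @param corpus A corpus tibble.
#' @return Tibble with `case_id`, `labels` (list-column) and `abstained`
#'   (no score reached the threshold).
#' @export
predict_labels <- function(model, corpus, augmented = TRUE, n_views = NULL,
                           seed = 1L, threshold = NULL) {
  threshold <- threshold %||% model$cfg$decision_threshold
  S <- predict_scores(model, corpus, augmented, n_views, seed)
  labs <- vocab_labels(model$vocab)
  sets <- lapply(seq_len(nrow(S)), function(i) labs[S[i, ] >= threshold])
  tibble(case_id = rownames(S), labels = sets,
         abstained = lengths(sets) == 0L)
}

#' Extract classification embeddings
#'
#' Returns the encoder-side representation the classification head consumes:
#' the trainable projection output, evaluated on the canonical
#' (stored-field-order) serialization in evaluation mode (no dropout).
#' Deterministic, and a pure function of the field text.
#'
#' @param model A fitted `synoptic_model`.
#' @param corpus A corpus tibble.
#' @return Numeric matrix, cases x `embed_dim`, with `case_id` rownames.
#' @export
extract_embedding <- function(model, corpus) {
  stopifnot(inherits(model, "synoptic_model"))
  corpus <- as_corpus(corpus)
  E <- forward_embedding(model, encode_corpus(corpus, model$cfg$encoder))
  rownames(E) <- corpus$case_id
  E
}

#' @export
print.synoptic_model <- function(x, ...) {
  cat("<synoptic_model> ", length(x$vocab), " labels, embed dim ",
      x$cfg$encoder$embed_dim, ", best epoch ", x$best_epoch,
      " (val micro-F1 ",
      sprintf("%.3f", x$trace$val_micro_f1[x$best_epoch]), ")\n", sep = "")
  invisible(x)
}

#' Per-epoch training trace of a fitted model
#' @param x A `synoptic_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_micro_f1`.
#' @exportS3Method generics::tidy
tidy.synoptic_model <- function(x, ...) x$trace

#' One-row model summary
#' @param x A `synoptic_model`.
#' @param ... Unused.
#' @return One-row tibble with the selected epoch and its validation
#'   micro-F1, plus model dimensions.
#' @exportS3Method generics::glance
glance.synoptic_model <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         val_micro_f1 = x$trace$val_micro_f1[x$best_epoch],
         epochs = nrow(x$trace),
         n_labels = length(x$vocab),
         embed_dim = x$cfg$encoder$embed_dim,
         buckets = x$cfg$encoder$buckets)
}

#' Training-trace plot
#' @param object A `synoptic_model`.
#' @param ... Unused.
#' @return A ggplot showing loss and validation micro-F1 per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.synoptic_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a fitted model as a plain-text artifact directory
#'
#' Writes the config (JSON), vocabulary (JSON), weight matrices (TSV) and
#' the per-epoch metric trace (CSV) so a fit can be archived or shipped
#' without binary files.
#'
#' @param model A `synoptic_model`.
#' @param dir Artifact directory (created if needed).
#' @rdname model_io
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$cfg
  cfg_json <- list(
    learning_rate = cfg$learning_rate, weight_decay = cfg$weight_decay,
    epochs = cfg$epochs, dropout = cfg$dropout, batch_size = cfg$batch_size,
    decision_threshold = cfg$decision_threshold, seed = cfg$seed,
    train_views = cfg$train_views, predict_views = cfg$predict_views,
    augment = cfg$augment, augmented_selection = cfg$augmented_selection,
    encoder = unclass(cfg$encoder), encoder_id = "hashing",
    best_epoch = model$best_epoch)
  writeLines(jsonlite::toJSON(cfg_json, auto_unbox = TRUE, digits = NA),
             file.path(dir, "config.json"))
  write_vocabulary(model$vocab, file.path(dir, "vocabulary.json"))
  for (p in c("W1", "b1", "W2", "b2")) {
    utils::write.table(model[[p]], file.path(dir, paste0(p, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(model$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname model_io
#' @export
load_model <- function(dir) {
  cfg_json <- jsonlite::fromJSON(file.path(dir, "config.json"))
  enc <- encoder_spec(cfg_json$encoder$buckets, cfg_json$encoder$embed_dim,
                      cfg_json$encoder$max_tokens, cfg_json$encoder$bigrams)
  cfg <- train_config(
    learning_rate = cfg_json$learning_rate,
    weight_decay = cfg_json$weight_decay, epochs = cfg_json$epochs,
    dropout = cfg_json$dropout, batch_size = cfg_json$batch_size,
    decision_threshold = cfg_json$decision_threshold, seed = cfg_json$seed,
    encoder = enc, train_views = cfg_json$train_views,
    predict_views = cfg_json$predict_views, augment = cfg_json$augment,
    augmented_selection = cfg_json$augmented_selection)
  rd <- function(p) as.matrix(utils::read.table(
    file.path(dir, paste0(p, ".tsv")), sep = "\t"))
  structure(list(
    W1 = unname(rd("W1")), b1 = as.numeric(rd("b1")),
    W2 = unname(rd("W2")), b2 = as.numeric(rd("b2")),
    vocab = read_vocabulary(file.path(dir, "vocabulary.json")),
    cfg = cfg,
    trace = as_tibble(read.csv(file.path(dir, "trace.csv"))),
    best_epoch = as.integer(cfg_json$best_epoch)),
    class = "synoptic_model")
}
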