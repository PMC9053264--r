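# Shared fixture builders. Everything is generated in code; heavyweight
# fits are memoized so several test files can share one trained model.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny hand-built labeled corpus (no generator) for mechanics tests
toy_corpus <- function() {
  corpus_tbl(
    case_id = c("a", "b", "c", "d"),
    fields = list(
      c(cellularity = "hypercellular marrow", comment = "blasts seen"),
      c(cellularity = "normal marrow", comment = "no concerns"),
      c(cellularity = "hypocellular marrow", comment = "blasts seen"),
      c(cellularity = "normal marrow", comment = "iron low")),
    labels = list(c("hyper", "blasts"), "normal", c("hypo", "blasts"),
                  c("normal", "iron")))
}

# balanced 5-label generator configuration (the classifier sanity corpus)
sanity_generator_config <- function(n_cases = 300, seed = 7) {
  labs5 <- default_generator_labels()
  labs5 <- labs5[labs5$label %in% c("normal", "iron_deficiency",
                                    "hypercellular", "erythroid_hyperplasia",
                                    "acute_myeloid_leukemia"), ]
  labs5$prior <- labs5$prior / sum(labs5$prior)
  generator_config(n_cases = n_cases, seed = seed, labels = labs5,
                   hidden_labels = character())
}

# 3-cluster configuration: three mutually exclusive labels, no extras
cluster3_generator_config <- function(n_cases = 150, seed = 5) {
  labs <- default_generator_labels()
  labs <- labs[labs$label %in% c("normal", "acute_myeloid_leukemia",
                                 "erythroid_hyperplasia"), ]
  labs$prior <- c(0.4, 0.3, 0.3)
  generator_config(n_cases = n_cases, seed = seed, labels = labs,
                   cooccur_pairs = tibble::tibble(a = character(),
                                                  b = character(),
                                                  prob = numeric()),
                   exception_rate = 0, extra_rate = 0,
                   hidden_labels = character())
}

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# one trained model on the 5-label sanity corpus, shared across test files
sanity_fit <- function() {
  memo("sanity_fit", {
    gen <- generate_corpus(sanity_generator_config())
    corpus <- clean_corpus(gen$corpus)
    model <- suppressWarnings(train_classifier(
      corpus[1:200, ], corpus[201:300, ], cfg = lightweight_config(seed = 11)))
    list(gen = gen, corpus = corpus, train = corpus[1:200, ],
         validation = corpus[201:300, ], model = model)
  })
}

# fast, low-accuracy training config for mechanics-only tests
quick_config <- function(...) {
  args <- utils::modifyList(
    list(epochs = 3L, batch_size = 8L,
         encoder = encoder_spec(buckets = 256L, embed_dim = 16L)),
    list(...))
  do.call(lightweight_config, args)
}

# Literal, independently written transcription of the adapted MCCV
# procedure, kept deliberately naive; the only shared convention with the
# implementation is that "shuffle" means sample() under the given seed.
mccv_reference <- function(corpus, ratio, seed) {
  n <- nrow(corpus)
  labels <- corpus$labels
  all_labels <- sort(unique(unlist(labels)))
  counts <- vapply(all_labels, function(l) {
    sum(vapply(labels, function(x) l %in% x, logical(1)))
  }, integer(1))
  min_val <- floor(min(counts) * ratio)
  val_size <- n * ratio
  set.seed(seed)
  ord <- sample.int(n)
  val <- integer(); tmp <- integer()
  vc <- stats::setNames(rep(0L, length(all_labels)), all_labels)
  for (i in ord) {
    if (any(vc[labels[[i]]] < min_val)) {
      val <- c(val, i)
      vc[labels[[i]]] <- vc[labels[[i]]] + 1L
    } else {
      tmp <- c(tmp, i)
    }
  }
  tmp <- tmp[sample.int(length(tmp))]
  train <- integer()
  for (i in tmp) {
    if (length(val) < val_size) val <- c(val, i) else train <- c(train, i)
  }
  list(train = corpus$case_id[train], validation = corpus$case_id[val],
       min_val = min_val)
}

balanced_corpus <- function(n_labels = 5, per_label = 10) {
  labs <- paste0("lab", seq_len(n_labels))
  ids <- sprintf("c%03d", seq_len(n_labels * per_label))
  corpus_tbl(ids,
             fields = rep(list(c(f = "text")), length(ids)),
             labels = as.list(rep(labs, each = per_label)))
}
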