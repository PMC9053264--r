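# Field-order shuffle augmentation.
#
# A synopsis is a set of field:description pairs whose order carries no
# meaning, so permuting the fields yields distinct text strings with the same
# semantics: extra training instances at train time, and multiple views whose
# per-label maximum is taken at prediction time.

#' Training-time field-shuffle augmentation
#'
#' Serializes each labeled case under `n_views` field permutations, drawn
#' without replacement while `n_views` does not exceed the number of distinct
#' permutations (beyond that, permutations repeat with replacement and a
#' warning is raised). Every view keeps the case's unchanged target labels.
#' Deterministic given `seed`.
#'
#' @param corpus A labeled corpus tibble.
#' @param n_views Number of views per case (>= 1).
#' @param seed Integer seed.
#' @param vocab Optional vocabulary; when given, a `target` list-column of
#'   0/1 vectors is attached.
#' @return Tibble with `case_id`, `view`, `text`, `labels` (and `target`).
#' @export
augment_training <- function(corpus, n_views = 3L, seed = 1L, vocab = NULL) {
  stopifnot(is_count(n_views))
  corpus <- labeled_cases(as_corpus(corpus))
  with_seed(seed, {
    views <- shuffle_views(corpus$fields, n_views, warn_replace = TRUE)
  })
  # shuffle_views emits views case-major: case 1's views first, then case 2's
  out <- tibble(
    case_id = corpus$case_id[views$case],
    view = rep(seq_len(n_views), nrow(corpus)),
    text = views$texts,
    labels = corpus$labels[views$case])
  if (!is.null(vocab)) {
    tm <- targets_matrix(out$labels, vocab)
    out$target <- lapply(seq_len(nrow(tm)), function(i) tm[i, ])
  }
  out
}

#' Augmented prediction over field-order views
#'
#' Applies `predict_fn` to `n_views` permuted serializations of one synopsis
#' and aggregates the per-label scores element-wise (maximum by default, so
#' each output component dominates every single view's score). With
#' exhaustive enumeration of the permutations the result is a pure function
#' of the field multiset, not the stored order.
#'
#' @param predict_fn Function mapping a serialized text string to a numeric
#'   score vector (one score per label, in `[0, 1]`).
#' @param fields Named character vector of one synopsis's fields.
#' @param n_views Number of views (>= 1). Permutations are drawn without
#'   replacement when possible; `n_views = NULL` enumerates all
#'   permutations.
#' @param seed Integer seed for the permutation draw.
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return Numeric score vector.
#' @export
augmented_predict <- function(predict_fn, fields, n_views = 5L, seed = 1L,
                              aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  k <- length(fields)
  perms <- if (is.null(n_views)) {
    all_permutations(k)
  } else {
    stopifnot(is_count(n_views))
    with_seed(seed, sample_permutations(k, n_views, warn_replace = FALSE))
  }
  scores <- lapply(seq_len(nrow(perms)), function(v) {
    s <- predict_fn(serialize_synopsis(fields, perms[v, ]))
    as.numeric(s)
  })
  if (length(unique(lengths(scores))) != 1L) {
    abort("predict_fn returned score vectors of differing lengths")
  }
  m <- do.call(rbind, scores)
  if (aggregate == "max") apply(m, 2, max) else colMeans(m)
}
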