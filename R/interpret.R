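# Word-knockout interpretability: remove one word from a synopsis, re-score,
# and attribute the per-label score change to that word. Per-word influence
# sums are grouped by the cases' gold labels and L2-normalized across labels.

# Remove every occurrence of a (case-folded, punctuation-stripped) word from
# each field description.
knockout_fields <- function(fields, word) {
  out <- vapply(unname(fields), function(desc) {
    toks <- strsplit(desc, "[[:space:]]+")[[1]]
    norm <- vapply(tokenize_words(toks), function(t) {
      paste(t, collapse = " ")
    }, character(1))
    paste(toks[norm != word], collapse = " ")
  }, character(1))
  names(out) <- names(fields)
  out
}

#' Per-label influence of one word on one case
#'
#' Scores the case on its canonical (stored-field-order, unaugmented)
#' serialization, then again with every occurrence of `word` removed from
#' the descriptions, and returns the per-label score difference
#' (original minus knocked-out). Since nothing else changes between the two
#' predictions, the difference is attributable to the word alone. A word
#' that does not occur yields an all-zero vector.
#'
#' @param model A fitted `synoptic_model`.
#' @param fields Named character vector of one synopsis's fields.
#' @param word A single case-folded, punctuation-stripped word token.
#' @return Named numeric vector of per-label deltas.
#' @export
knockout_case <- function(model, fields, word) {
  stopifnot(inherits(model, "synoptic_model"), length(word) == 1)
  spec <- model$cfg$encoder
  toks <- unique(unlist(tokenize_words(unname(fields))))
  labs <- vocab_labels(model$vocab)
  if (!word %in% toks) {
    return(setNames(numeric(length(labs)), labs))
  }
  texts <- c(serialize_synopsis(fields),
             serialize_synopsis(knockout_fields(fields, word)))
  S <- forward_scores(model, encode_features(texts, spec))
  setNames(S[1, ] - S[2, ], labs)
}

#' Build the word-influence table over a labeled corpus
#'
#' For every word occurring in any description, computes the knockout delta
#' on every case containing it; a case's delta for label Y contributes to
#' `(word, Y)` only when Y is one of that case's gold labels. The per-label
#' sums of each word are then divided by the L2 norm of the word's
#' across-label sum vector, so each observed word's normalized influence
#' vector has unit length.
#'
#' @param model A fitted `synoptic_model`.
#' @param corpus Labeled corpus tibble.
#' @param signed Sum signed deltas (default, "the change"); `FALSE` sums
#'   magnitudes instead.
#' @param predict_fn Optional override mapping a character vector of texts
#'   to a score matrix (rows = texts); used for oracle testing with mock
#'   predictors.
#' @return An `influence_table` tibble with `word`, `label`, `raw_sum`,
#'   `norm`, `support`.
#' @export
influence_table <- function(model, corpus, signed = TRUE,
                            predict_fn = NULL) {
  corpus <- labeled_cases(as_corpus(corpus))
  if (!nrow(corpus)) abort("influence scoring needs a labeled corpus")
  if (is.null(predict_fn)) {
    stopifnot(inherits(model, "synoptic_model"))
    spec <- model$cfg$encoder
    predict_fn <- function(texts) forward_scores(model,
                                                 encode_features(texts, spec))
    labs <- vocab_labels(model$vocab)
  } else {
    labs <- vocab_labels(model)
  }

  acc <- new.env(parent = emptyenv())
  acc$raw <- list()
  acc$support <- list()
  add <- function(word, label, delta) {
    key <- paste0(word, "\r", label)
    acc$raw[[key]] <- (acc$raw[[key]] %||% 0) + delta
    acc$support[[key]] <- (acc$support[[key]] %||% 0L) + 1L
  }

  for (i in seq_len(nrow(corpus))) {
    fields <- corpus$fields[[i]]
    gold <- corpus$labels[[i]]
    words <- unique(unlist(tokenize_words(unname(fields))))
    if (!length(words)) next
    texts <- c(serialize_synopsis(fields),
               vapply(words, function(w) {
                 serialize_synopsis(knockout_fields(fields, w))
               }, character(1)))
    S <- predict_fn(texts)
    colnames(S) <- labs
    base <- S[1, ]
    for (j in seq_along(words)) {
      delta <- base - S[j + 1L, ]
      if (!signed) delta <- abs(delta)
      for (y in gold) add(words[j], y, delta[[y]])
    }
  }

  keys <- names(acc$raw)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- tibble(
    word = vapply(parts, `[`, character(1), 1L),
    label = vapply(parts, `[`, character(1), 2L),
    raw_sum = unlist(acc$raw, use.names = FALSE),
    support = unlist(acc$support, use.names = FALSE))
  out <- out |>
    group_by(.data$word) |>
    mutate(norm = {
      l2 <- sqrt(sum(.data$raw_sum^2))
      if (l2 == 0) .data$raw_sum * 0 else .data$raw_sum / l2
    }) |>
    ungroup() |>
    arrange(.data$word, .data$label)
  class(out) <- c("influence_table", class(out))
  out
}

#' Top-k influential words for a label
#'
#' @param table An [influence_table()].
#' @param label A vocabulary label.
#' @param k Number of words (default 5).
#' @return Character vector of the k words with the highest normalized
#'   influence for the label, descending; ties broken lexicographically. A
#'   label with no entries yields an empty vector.
#' @export
top_k_words <- function(table, label, k = 5L) {
  sub <- table[table$label == label, , drop = FALSE]
  if (!nrow(sub)) return(character())
  sub <- sub[order(-sub$norm, sub$word), , drop = FALSE]
  utils::head(sub$word, k)
}

#' Export an influence table as a words-by-labels matrix
#'
#' @param table An [influence_table()].
#' @param value Which column to spread (default `"norm"`).
#' @return Numeric matrix, words x labels (absent pairs are 0), suitable for
#'   heatmap rendering.
#' @export
influence_matrix <- function(table, value = "norm") {
  wide <- tidyr::pivot_wider(table[, c("word", "label", value)],
                             names_from = "label",
                             values_from = tidyr::all_of(value),
                             values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$word
  m
}
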