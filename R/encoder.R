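# Feature-hashing text encoder.
#
# The classifier consumes a fixed-width representation of the serialized
# synopsis text: case-folded word tokens and consecutive-token bigrams are
# hashed into a fixed number of buckets and the resulting count vector is
# L2-normalized. Bigrams make the representation sensitive to serialization
# order (a pure bag of words would make field-order shuffling a no-op), which
# is what lets field-shuffle augmentation act as a regularizer.

#' Encoder settings
#'
#' @param buckets Number of hash buckets (feature width of the token layer).
#' @param embed_dim Width of the trainable projection (the classification
#'   embedding returned by [extract_embedding()]).
#' @param max_tokens Maximum tokens kept per text; longer texts are truncated
#'   with a warning.
#' @param bigrams Also hash consecutive-token bigrams.
#' @param bigram_weight Relative weight of bigram counts against unigram
#'   counts. Bigram sequences inside a field are nearly unique per case, so
#'   at full weight they act as case fingerprints the classifier can
#'   memorize; the default keeps them as a mild order-sensitive signal.
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(buckets = 1024L, embed_dim = 64L, max_tokens = 256L,
                         bigrams = TRUE, bigram_weight = 0.1) {
  stopifnot(is_count(buckets), is_count(embed_dim), is_count(max_tokens),
            bigram_weight >= 0)
  structure(list(buckets = as.integer(buckets),
                 embed_dim = as.integer(embed_dim),
                 max_tokens = as.integer(max_tokens),
                 bigrams = isTRUE(bigrams),
                 bigram_weight = bigram_weight),
            class = "encoder_spec")
}

#' Tokenize one text into the padded id/mask representation
#'
#' Deterministic tokenization of a single text into the encoder input
#' contract: a classification position (id 1) followed by hashed token ids,
#' right-padded with 0 to `max_tokens + 1`. `attention_mask` is 1 exactly on
#' the non-padding positions; `segment_ids` are all 0 (single-segment input).
#' Texts longer than `max_tokens` are truncated with a warning.
#'
#' @param text A single string.
#' @param spec An [encoder_spec()].
#' @return List with `token_ids`, `attention_mask`, `segment_ids`.
#' @export
encode_text <- function(text, spec = encoder_spec()) {
  stopifnot(length(text) == 1, !is.null(text))
  toks <- tokenize_words(text)[[1]]
  if (length(toks) > spec$max_tokens) {
    warn(sprintf("text truncated from %d to %d tokens",
                 length(toks), spec$max_tokens))
    toks <- toks[seq_len(spec$max_tokens)]
  }
  ids <- if (length(toks)) hash_tokens(toks, spec$buckets) + 1L else integer()
  len <- spec$max_tokens + 1L
  token_ids <- c(1L, ids, rep(0L, len - 1L - length(ids)))
  mask <- as.integer(token_ids != 0L)
  mask[1] <- 1L
  list(token_ids = token_ids, attention_mask = mask,
       segment_ids = rep(0L, len))
}

# Hash a batch of texts into an n x buckets L2-normalized count matrix.
encode_features <- function(texts, spec = encoder_spec()) {
  n <- length(texts)
  if (n == 0L) return(matrix(0, 0L, spec$buckets))
  toks <- tokenize_words(texts)
  over <- lengths(toks) > spec$max_tokens
  if (any(over)) {
    warn(sprintf("%d text(s) truncated to %d tokens", sum(over),
                 spec$max_tokens))
    toks[over] <- lapply(toks[over], function(t) t[seq_len(spec$max_tokens)])
  }
  flat <- unlist(toks, use.names = FALSE)
  i <- rep(seq_len(n), lengths(toks))
  x <- rep(1, length(flat))
  if (spec$bigrams && spec$bigram_weight > 0) {
    bi <- lapply(toks, function(t) {
      if (length(t) < 2L) character() else paste(t[-length(t)], t[-1L],
                                                 sep = "\r")
    })
    flat <- c(flat, unlist(bi, use.names = FALSE))
    i <- c(i, rep(seq_len(n), lengths(bi)))
    x <- c(x, rep(spec$bigram_weight, sum(lengths(bi))))
  }
  if (!length(flat)) return(matrix(0, n, spec$buckets))
  uniq <- unique(flat)
  ids <- hash_tokens(uniq, spec$buckets)
  m <- as.matrix(Matrix::sparseMatrix(i = i, j = ids[match(flat, uniq)],
                                      x = x, dims = c(n, spec$buckets)))
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# Canonical (stored field order) features for a corpus.
encode_corpus <- function(corpus, spec) {
  encode_features(serialize_corpus(as_corpus(corpus)), spec)
}
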