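# Train/validation splitting: the active-learning-stage split (at least one
# case per label in training, then 80/20 overall) and the adapted Monte Carlo
# cross-validation that guarantees a per-label minimum in validation.

new_split_result <- function(train_ids, validation_ids, ratio,
                             min_val_per_label, seed) {
  structure(list(train_ids = train_ids, validation_ids = validation_ids,
                 ratio = ratio, min_val_per_label = min_val_per_label,
                 seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> train ", length(x$train_ids), " / validation ",
      length(x$validation_ids), " (ratio ", x$ratio,
      ", min per label ", x$min_val_per_label, ")\n", sep = "")
  invisible(x)
}

#' Active-learning-stage split
#'
#' First assigns at least one case per vocabulary label to training (so a
#' model trained during the active-learning stage has seen every label),
#' then splits the remaining cases at random to reach the overall
#' train/validation proportion. If the per-label constraint saturates the
#' corpus, validation may be empty (with a warning). Deterministic by seed.
#'
#' @param corpus A labeled corpus tibble.
#' @param ratio Validation fraction (default 0.2 for an 80/20 split).
#' @param seed Integer seed.
#' @param vocab Optional [label_vocabulary()]; every label must have at
#'   least one case.
#' @return A `split_result` with disjoint `train_ids` / `validation_ids`
#'   covering the corpus.
#' @export
al_stage_split <- function(corpus, ratio = 0.2, seed = 1L, vocab = NULL) {
  corpus <- labeled_cases(as_corpus(corpus))
  if (!nrow(corpus)) abort("corpus has no labeled cases")
  if (ratio <= 0 || ratio >= 1) abort("ratio must be in (0, 1)")
  labs <- if (is.null(vocab)) unique(unlist(corpus$labels))
          else vocab_labels(vocab)
  counts <- label_counts(corpus, labs)
  if (any(counts$n == 0L)) {
    abort(paste0("labels with zero cases: ",
                 paste(counts$label[counts$n == 0L], collapse = ", ")))
  }
  ids <- corpus$case_id
  case_labels <- setNames(corpus$labels, ids)
  with_seed(seed, {
    train <- character()
    # rarest labels claim their mandatory training case first
    for (lab in counts$label[order(counts$n, counts$label)]) {
      if (any(vapply(case_labels[train], function(l) lab %in% l,
                     logical(1)))) next
      carriers <- ids[vapply(case_labels, function(l) lab %in% l,
                             logical(1))]
      pick <- if (length(carriers) == 1L) carriers
              else sample(carriers, 1L)
      train <- c(train, pick)
    }
    rest <- setdiff(ids, train)
    n_val <- round(length(ids) * ratio)
    if (n_val > length(rest)) {
      warn("per-label training constraint saturated the corpus; validation smaller than requested")
      n_val <- length(rest)
    }
    val <- if (n_val > 0) sample(rest, n_val) else character()
    train <- c(train, setdiff(rest, val))
  })
  new_split_result(train, val, ratio, 1L, seed)
}

#' Adapted Monte Carlo cross-validation split
#'
#' One split of the adapted MCCV procedure: with
#' `min_val_per_label = floor(min(label counts) * ratio)`, a first pass over
#' the shuffled cases sends a case to validation if any of its labels is
#' still below that minimum there; a second pass over the reshuffled
#' remainder fills validation up to `n * ratio`, and everything else goes to
#' training. Every label is therefore guaranteed at least
#' `min_val_per_label` validation cases. If the first pass overfills
#' validation beyond the target size the overfill stands. Deterministic by
#' seed.
#'
#' @param corpus A labeled corpus tibble.
#' @param ratio Validation fraction in (0, 1); a ratio giving validation
#'   size zero is an error.
#' @param seed Integer seed.
#' @return A `split_result`.
#' @export
mccv_split <- function(corpus, ratio, seed = 1L) {
  corpus <- labeled_cases(as_corpus(corpus))
  if (!nrow(corpus)) abort("corpus has no labeled cases")
  if (ratio <= 0 || ratio >= 1) abort("ratio must be in (0, 1)")
  n <- nrow(corpus)
  val_size <- n * ratio
  if (floor(val_size) < 1) abort("requested validation size is zero")
  counts <- label_counts(corpus)
  min_val <- floor(min(counts$n) * ratio)
  if (min_val < 1) {
    inform("rarest label too small for the ratio; per-label validation minimum is 0")
  }
  labels <- corpus$labels
  ids <- corpus$case_id
  with_seed(seed, {
    ord <- sample.int(n)
    val <- integer()
    tmp <- integer()
    val_counts <- setNames(integer(length(counts$n)), counts$label)
    for (i in ord) {
      labs <- labels[[i]]
      if (any(val_counts[labs] < min_val)) {
        val <- c(val, i)
        val_counts[labs] <- val_counts[labs] + 1L
      } else {
        tmp <- c(tmp, i)
      }
    }
    tmp <- tmp[sample.int(length(tmp))]
    train <- integer()
    for (i in tmp) {
      if (length(val) < val_size) val <- c(val, i) else train <- c(train, i)
    }
  })
  new_split_result(ids[train], ids[val], ratio, min_val, seed)
}

#' Repeated adapted MCCV
#'
#' Independent [mccv_split()] per seed, e.g. to build the final
#' training/validation datasets behind an ensemble of models whose
#' validation scores are reported as mean and spread.
#'
#' @param corpus A labeled corpus tibble.
#' @param ratio Validation fraction.
#' @param seeds Integer vector of seeds (one split per seed).
#' @return List of `split_result`s.
#' @export
repeat_mccv <- function(corpus, ratio, seeds) {
  if (!length(seeds)) abort("need at least one seed")
  lapply(seeds, function(s) mccv_split(corpus, ratio, s))
}

#' Write / read a split manifest (JSON)
#' @param split A `split_result`.
#' @param path File path.
#' @rdname split_io
#' @export
write_split <- function(split, path) {
  writeLines(jsonlite::toJSON(list(
    train = split$train_ids, validation = split$validation_ids,
    seed = split$seed, ratio = split$ratio), auto_unbox = TRUE, digits = NA),
    path)
  invisible(path)
}

#' @rdname split_io
#' @export
read_split <- function(path) {
  x <- jsonlite::fromJSON(path)
  new_split_result(as.character(x$train), as.character(x$validation),
                   x$ratio, NA_integer_, x$seed)
}

# subset helper
split_corpus <- function(corpus, split) {
  corpus <- as_corpus(corpus)
  list(train = corpus[match(split$train_ids, corpus$case_id), ],
       validation = corpus[match(split$validation_ids, corpus$case_id), ])
}
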