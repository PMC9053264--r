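# Rare-label (CRL) active learning: iteratively train, predict the unlabeled
# pool, sample cases predicted to carry rare labels, send them to a labelling
# oracle, and merge the verified answers — growing both the labeled corpus
# and (through label discovery) the vocabulary, until every label has at
# least the threshold number of labeled cases.

#' Labels with fewer labeled cases than a threshold
#'
#' @param corpus A labeled corpus tibble.
#' @param vocab A [label_vocabulary()] or character vector.
#' @param threshold Positive integer; a label is rare when its labeled count
#'   is strictly below it.
#' @return Character vector of rare labels.
#' @export
find_rare_labels <- function(corpus, vocab, threshold) {
  stopifnot(is_count(threshold))
  counts <- label_counts(as_corpus(corpus), vocab)
  counts$label[counts$n < threshold]
}

#' Sample cases-with-rare-labels (CRL) candidates
#'
#' For each rare label, draws `threshold - count(label)` pool cases
#' uniformly at random from the label's predicted group: the pool cases
#' whose score for that label reaches the decision threshold. Rare labels
#' are processed in ascending count order (the rarest claims candidates
#' first) and a case already claimed is not drawn again, so a pool case
#' appears at most once in the returned set.
#'
#' If a predicted group has fewer cases than requested, all of them are
#' taken and the shortfall is recorded in the `shortfall` attribute. With
#' `rank_fallback = TRUE` the remainder is instead filled with the unclaimed
#' pool cases scoring highest for the label — a rank-based notion of the
#' predicted group that lets the loop bootstrap labels the current model is
#' not yet confident about (a model trained on two or three cases of a label
#' usually ranks its true cases high long before any of them crosses the
#' threshold).
#'
#' @param scores Numeric pool-by-labels score matrix with case-id rownames
#'   (e.g. from [predict_scores()]).
#' @param rare Character vector of rare labels.
#' @param threshold Working threshold.
#' @param counts Tibble of current labeled counts (`label`, `n`), as from
#'   [label_counts()].
#' @param seed Integer seed.
#' @param decision_threshold Score cutoff defining predicted group
#'   membership.
#' @param rank_fallback Fill undersized predicted groups by score rank.
#' @return Character vector of candidate case ids, with a named
#'   `shortfall` attribute (requested minus obtained per label).
#' @export
sample_crl <- function(scores, rare, threshold, counts, seed = 1L,
                       decision_threshold = 0.5, rank_fallback = FALSE) {
  stopifnot(is_count(threshold), is.matrix(scores))
  ids <- rownames(scores)
  cnt <- setNames(counts$n, counts$label)
  rare <- rare[order(ifelse(is.na(cnt[rare]), 0L, cnt[rare]), rare)]
  chosen <- character()
  shortfall <- c()
  with_seed(seed, {
    for (lab in rare) {
      have <- if (is.na(cnt[lab])) 0L else cnt[lab]
      need <- threshold - have
      if (need <= 0L || !lab %in% colnames(scores)) next
      s <- scores[, lab]
      group <- ids[s >= decision_threshold]
      group <- setdiff(group, chosen)
      if (length(group) >= need) {
        take <- if (length(group) == 1L) group else sample(group, need)
      } else {
        take <- group
        if (rank_fallback) {
          rest <- setdiff(ids, c(chosen, take))
          rest <- rest[order(-s[match(rest, ids)])]
          take <- c(take, head(rest, need - length(take)))
        }
        if (length(take) < need) shortfall[lab] <- need - length(take)
      }
      chosen <- c(chosen, take)
    }
  })
  attr(chosen, "shortfall") <- shortfall
  chosen
}

#' Initialize an active-learning state
#'
#' @param pool Unlabeled corpus tibble (the raw data).
#' @param labeled Labeled corpus tibble (the current development dataset).
#' @param vocab A [label_vocabulary()].
#' @param threshold Base rare-label threshold (default 20).
#' @return An `al_state`.
#' @export
al_state <- function(pool, labeled, vocab, threshold = 20L) {
  pool <- as_corpus(pool)
  labeled <- as_corpus(labeled)
  overlap <- intersect(pool$case_id, labeled$case_id)
  if (length(overlap)) abort("pool and labeled sets must be disjoint")
  structure(list(pool = pool, labeled = labeled, vocab = vocab,
                 threshold = as.integer(threshold), iteration = 0L,
                 history = tibble(), models = list(),
                 converged = FALSE, shortfall = character()),
            class = "al_state")
}

#' @export
print.al_state <- function(x, ...) {
  cat("<al_state> iteration ", x$iteration, ": ", nrow(x$labeled),
      " labeled / ", nrow(x$pool), " pool, ", length(x$vocab),
      " labels", if (x$converged) " (converged)", "\n", sep = "")
  invisible(x)
}

#' One active-learning iteration
#'
#' Trains a model on the current labeled set (via [al_stage_split()] and
#' [train_classifier()]), predicts the pool, samples CRL candidates at the
#' working threshold, and — while the candidate set exceeds `cap` — lowers
#' the working threshold by `decrement` and resamples. The candidates are
#' submitted to the oracle; verified cases join the labeled set, leave the
#' pool, and any newly revealed labels are appended to the vocabulary.
#'
#' @param state An [al_state()].
#' @param oracle A `label_oracle`.
#' @param cfg A [train_config()] for the per-iteration model.
#' @param threshold Target threshold for this iteration (defaults to the
#'   state's base threshold).
#' @param cap Maximum candidate-set size submitted to the oracle (100).
#' @param decrement Threshold decrement applied while over the cap (5).
#' @param seed Integer seed for this iteration's sampling.
#' @param pool_features Optional cached canonical feature matrix of the pool
#'   (rows in pool order) to avoid re-encoding on every iteration.
#' @param rank_fallback Passed to [sample_crl()]; on by default so early
#'   weak models can still surface candidates for barely-seen labels.
#' @param exclude_labels Rare labels to skip this iteration (e.g. labels the
#'   pool has been unable to supply).
#' @return The updated `al_state` (history gains one row; the trained model
#'   is kept in `state$models` under the iteration number).
#' @export
run_iteration <- function(state, oracle, cfg = train_config(),
                          threshold = NULL, cap = 100L, decrement = 5L,
                          seed = 1L, pool_features = NULL,
                          rank_fallback = TRUE,
                          exclude_labels = character()) {
  stopifnot(inherits(state, "al_state"), inherits(oracle, "label_oracle"))
  threshold <- as.integer(threshold %||% state$threshold)
  state$iteration <- state$iteration + 1L
  counts <- label_counts(state$labeled, state$vocab)
  rare <- setdiff(find_rare_labels(state$labeled, state$vocab, threshold),
                  exclude_labels)
  if (!length(rare) || !nrow(state$pool)) {
    state$history <- bind_rows(state$history, tibble(
      iteration = state$iteration, threshold = threshold,
      working_threshold = threshold, n_candidates = 0L, n_added = 0L,
      n_new_labels = 0L, n_labels = length(state$vocab),
      n_labeled = nrow(state$labeled)))
    return(state)
  }

  split <- al_stage_split(state$labeled, ratio = 0.2, seed = seed,
                          vocab = state$vocab)
  parts <- split_corpus(state$labeled, split)
  if (!nrow(parts$validation)) {
    # constraint saturated the labeled set: hold out a random 20% instead
    # so best-epoch selection still has a yardstick
    split2 <- with_seed(seed, sample(state$labeled$case_id,
                                     max(1L, round(0.2 * nrow(state$labeled)))))
    parts$validation <- state$labeled[state$labeled$case_id %in% split2, ]
  }
  model <- suppressWarnings(
    train_classifier(parts$train, parts$validation, state$vocab, cfg))

  scores <- if (is.null(pool_features)) {
    predict_scores(model, state$pool, augmented = FALSE)
  } else {
    S <- forward_scores(model, pool_features)
    dimnames(S) <- list(state$pool$case_id, vocab_labels(state$vocab))
    S
  }

  working <- threshold
  candidates <- sample_crl(scores, rare, working, counts, seed,
                           cfg$decision_threshold, rank_fallback)
  while (length(candidates) > cap) {
    working <- working - as.integer(decrement)
    if (working < 1L) abort("candidate cap drove the working threshold below 1")
    rare_w <- setdiff(
      find_rare_labels(state$labeled, state$vocab, working), exclude_labels)
    candidates <- sample_crl(scores, rare_w, working, counts, seed,
                             cfg$decision_threshold, rank_fallback)
  }

  n_new <- 0L
  added <- 0L
  if (length(candidates)) {
    ans <- oracle$query(candidates)
    new_labels <- union(attr(ans, "new_labels") %||% character(),
                        setdiff(unique(unlist(ans$labels)),
                                vocab_labels(state$vocab)))
    n_new <- length(new_labels)
    state$vocab <- add_labels(state$vocab, new_labels)
    keep <- match(ans$case_id, state$pool$case_id)
    newly <- state$pool[keep, ]
    newly$labels <- ans$labels[match(newly$case_id, ans$case_id)]
    state$labeled <- bind_rows(state$labeled, newly)
    state$pool <- state$pool[-keep, ]
    added <- nrow(newly)
  }

  state$models[[as.character(state$iteration)]] <- model
  state$history <- bind_rows(state$history, tibble(
    iteration = state$iteration, threshold = threshold,
    working_threshold = working, n_candidates = length(candidates),
    n_added = added, n_new_labels = n_new,
    n_labels = length(state$vocab), n_labeled = nrow(state$labeled)))
  state
}

#' Run the full rare-label active-learning loop
#'
#' Seeds the labeled set with `initial_n` randomly sampled oracle-labeled
#' cases, then iterates [run_iteration()] under the threshold schedule
#' (early iterations use the lowered thresholds, later iterations the final
#' one) until no label is rare at the final threshold — the loop's
#' termination contract — or until the pool, the labeling budget, or
#' `max_iter` is exhausted. When the oracle's pool cannot supply a label up
#' to the final threshold, the run terminates with those labels recorded in
#' `$shortfall` rather than looping forever.
#'
#' @param pool Unlabeled corpus tibble.
#' @param oracle A `label_oracle`. If it provides `initial_sample`, the seed
#'   set is drawn through it (the synthetic oracle withholds hidden-label
#'   cases there, so hidden labels must be *discovered*).
#' @param initial_n Size of the initial random sample (default 50).
#' @param schedule Integer thresholds per iteration phase; iteration `i`
#'   uses `schedule[min(i, length(schedule))]`, so the last entry is the
#'   final threshold (default `c(10, 15, 20)`).
#' @param cfg A [train_config()].
#' @param cap,decrement Candidate cap and threshold decrement, as in
#'   [run_iteration()].
#' @param seed Integer master seed; per-iteration seeds are derived from it.
#' @param max_iter Safety bound on iterations.
#' @param max_labeled Optional labeling budget; the loop stops once the
#'   labeled set reaches it.
#' @param grow_to_budget With a finite `max_labeled`: once every label meets
#'   the final threshold, keep raising the threshold by `decrement` and
#'   enriching until the budget is spent — the stated continuation rule when
#'   more annotation is judged worthwhile. Used to build
#'   active-learning-selected training sets of a fixed size for comparison
#'   against random sampling.
#' @return The final `al_state`, with `$converged`, `$shortfall`, `$history`
#'   and the per-iteration models.
#' @export
run_active_learning <- function(pool, oracle, initial_n = 50L,
                                schedule = c(10L, 15L, 20L),
                                cfg = train_config(), cap = 100L,
                                decrement = 5L, seed = 1L, max_iter = 40L,
                                max_labeled = Inf, grow_to_budget = FALSE) {
  pool <- as_corpus(pool)
  if (nrow(pool) <= initial_n) abort("pool must exceed the initial sample")
  final_threshold <- as.integer(schedule[length(schedule)])

  init_ids <- if (!is.null(oracle$initial_sample)) {
    oracle$initial_sample(initial_n, seed, from = pool$case_id)
  } else {
    with_seed(seed, sample(pool$case_id, initial_n))
  }
  ans <- oracle$query(init_ids)
  labeled <- pool[match(ans$case_id, pool$case_id), ]
  labeled$labels <- ans$labels
  pool <- pool[!pool$case_id %in% ans$case_id, ]
  vocab <- label_vocabulary(sort(unique(unlist(ans$labels))))

  base_threshold <- final_threshold
  state <- al_state(pool, labeled, vocab, final_threshold)
  spec <- cfg$encoder
  pool_feat <- encode_corpus(state$pool, spec)
  pool_ids <- state$pool$case_id

  # a rare label whose count stops moving for `stall_limit` straight
  # iterations at the final threshold is treated as pool-exhausted
  stall_limit <- 3L
  stalled <- integer(0)

  for (i in seq_len(max_iter)) {
    thr <- if (i <= length(schedule)) schedule[i] else final_threshold
    exhausted <- names(stalled)[stalled >= stall_limit]
    rare_final <- setdiff(
      find_rare_labels(state$labeled, state$vocab, final_threshold),
      exhausted)
    if (thr >= final_threshold && !length(rare_final)) {
      if (grow_to_budget && is.finite(max_labeled) &&
          nrow(state$labeled) < max_labeled && nrow(state$pool)) {
        final_threshold <- final_threshold + as.integer(decrement)
        thr <- final_threshold
      } else {
        break
      }
    }
    if (!nrow(state$pool) || nrow(state$labeled) >= max_labeled) break
    feat <- pool_feat[match(state$pool$case_id, pool_ids), , drop = FALSE]
    before <- label_counts(state$labeled, state$vocab)
    state <- run_iteration(state, oracle, cfg, threshold = thr, cap = cap,
                           decrement = decrement,
                           seed = (seed * 131L + i) %% 2147483647L,
                           pool_features = feat, exclude_labels = exhausted)
    after <- label_counts(state$labeled, state$vocab)
    rare_now <- find_rare_labels(state$labeled, state$vocab, thr)
    for (lab in rare_now) {
      b <- before$n[match(lab, before$label)]
      a <- after$n[match(lab, after$label)]
      if (!is.na(b) && a == b) {
        stalled[lab] <- (if (lab %in% names(stalled)) stalled[lab] else 0L) + 1L
      } else {
        stalled[lab] <- 0L
      }
    }
  }

  rare_final <- find_rare_labels(state$labeled, state$vocab, base_threshold)
  state$converged <- !length(rare_final)
  state$shortfall <- rare_final
  if (length(rare_final)) {
    inform(paste0("active learning stopped short of the threshold for: ",
                  paste(rare_final, collapse = ", ")))
  }
  state
}

#' Random-sampling baseline
#'
#' Uniformly samples `budget` pool cases and labels them through the oracle:
#' the comparison arm for active-learning experiments.
#'
#' @param pool Unlabeled corpus tibble.
#' @param oracle A `label_oracle`.
#' @param budget Number of cases to label (at most the pool size).
#' @param seed Integer seed.
#' @return A labeled corpus tibble.
#' @export
random_baseline <- function(pool, oracle, budget, seed = 1L) {
  pool <- as_corpus(pool)
  if (budget > nrow(pool)) abort("budget exceeds the pool size")
  ids <- with_seed(seed, sample(pool$case_id, budget))
  ans <- oracle$query(ids)
  out <- pool[match(ans$case_id, pool$case_id), ]
  out$labels <- ans$labels
  out
}
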