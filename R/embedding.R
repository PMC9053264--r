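# Embedding-space analyses: corpus embedding, 2-D projection (t-SNE or PCA)
# for cluster inspection, silhouette and kNN diagnostics, and predicted-label
# co-occurrence matrices for chord-diagram export.

#' Embed every case of a corpus
#'
#' One classification embedding per case ([extract_embedding()]), in corpus
#' order; deterministic given the model and input.
#'
#' @param model A fitted `synoptic_model`.
#' @param corpus A corpus tibble.
#' @return Numeric matrix (cases x embed_dim) with `case_id` rownames.
#' @export
embed_corpus <- function(model, corpus) {
  extract_embedding(model, corpus)
}

# Exact t-SNE (O(n^2)): conditional perplexity calibration by binary search,
# early exaggeration, momentum gradient descent with adaptive gains.
tsne_exact <- function(X, perplexity = 30, max_iter = 400, seed = 1L,
                       eta = 100, exaggeration = 12, exag_iter = 100) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) { H <- 0; p <- p * 0 } else {
        H <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  })
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    if (iter == exag_iter + 1) Pe <- P
    if (iter == 21) momentum <- 0.8
    sum_y2 <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y2, sum_y2, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Project embeddings to two dimensions
#'
#' Seeded, reproducible 2-D coordinates for cluster inspection: exact t-SNE
#' (default; perplexity 30, capped at `(n-1)/3` for small inputs) or PCA.
#'
#' @param embeddings Numeric matrix (cases x dims) with optional `case_id`
#'   rownames; at least two rows.
#' @param method `"tsne"` or `"pca"`.
#' @param seed Integer seed (t-SNE initialization).
#' @param perplexity t-SNE perplexity.
#' @param max_iter t-SNE gradient-descent iterations.
#' @param labels Optional per-case annotation (e.g. collapsed gold labels)
#'   carried into the output.
#' @return Tibble with `case_id`, `x`, `y` (and `labels` if given).
#' @export
project_2d <- function(embeddings, method = c("tsne", "pca"), seed = 1L,
                       perplexity = 30, max_iter = 400, labels = NULL) {
  method <- match.arg(method)
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2) abort("need at least two cases to project")
  Y <- switch(method,
    tsne = tsne_exact(embeddings, perplexity, max_iter, seed),
    pca = {
      p <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
      k <- min(2L, ncol(p$x))
      cbind(p$x[, 1], if (k == 2) p$x[, 2] else 0)
    })
  out <- tibble(case_id = rownames(embeddings) %||%
                  as.character(seq_len(n)),
                x = Y[, 1], y = Y[, 2])
  if (!is.null(labels)) out$labels <- labels
  out
}

#' Mean silhouette of label groups in embedding space
#'
#' Average silhouette width of the given grouping under Euclidean distance;
#' positive values mean cases sit closer to their own label group than to
#' the nearest other group.
#'
#' @param embeddings Numeric matrix (cases x dims).
#' @param groups Character/factor grouping (at least two distinct values).
#' @return A single number in `[-1, 1]`.
#' @export
embedding_silhouette <- function(embeddings, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need at least two groups")
  D <- as.matrix(stats::dist(embeddings))
  n <- nrow(D)
  sil <- vapply(seq_len(n), function(i) {
    own <- groups == groups[i]
    if (sum(own) == 1L) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g) {
      mean(D[i, groups == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' kNN label agreement in a 2-D projection
#'
#' Fraction of cases whose k nearest neighbours (Euclidean) share their
#' label, averaged over cases; compare against [permuted_knn_baseline()] to
#' judge whether a projection clusters by label beyond chance.
#'
#' @param coords Numeric matrix or `project_2d()` tibble.
#' @param labels Character per-case labels.
#' @param k Neighbourhood size (default 5).
#' @return Mean per-case agreement in `[0, 1]`.
#' @export
knn_label_agreement <- function(coords, labels, k = 5L) {
  if (is.data.frame(coords)) coords <- cbind(coords$x, coords$y)
  labels <- as.character(labels)
  n <- nrow(coords)
  stopifnot(length(labels) == n, n > k)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1)))
}

#' Permuted-label kNN baseline
#'
#' The same agreement statistic after randomly permuting the labels,
#' averaged over `n_perm` seeded permutations: the chance level for
#' [knn_label_agreement()].
#'
#' @inheritParams knn_label_agreement
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Mean permuted agreement.
#' @export
permuted_knn_baseline <- function(coords, labels, k = 5L, n_perm = 20L,
                                  seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(n_perm), function(p) {
      knn_label_agreement(coords, sample(labels), k)
    }, numeric(1)))
  })
}

#' Predicted-label co-occurrence matrix
#'
#' `counts[i, j]` is the number of cases predicted to carry both labels i
#' and j; the diagonal holds per-label prediction totals. Symmetric, with
#' every off-diagonal entry bounded by the two diagonal entries; this is
#' the matrix a chord diagram of predicted label co-occurrence renders.
#'
#' @param predictions Tibble with `case_id` and `labels` list-column (e.g.
#'   [predict_labels()] output), or a list of label sets.
#' @param vocab A [label_vocabulary()] or character vector.
#' @return Integer matrix (labels x labels) of class `cooccurrence_matrix`.
#' @export
cooccurrence <- function(predictions, vocab) {
  labs <- vocab_labels(vocab)
  sets <- if (is.data.frame(predictions)) predictions$labels else predictions
  unknown <- setdiff(unique(unlist(sets)), labs)
  if (length(unknown)) {
    abort(paste0("predicted labels not in vocabulary: ",
                 paste(unknown, collapse = ", ")))
  }
  M <- targets_matrix(sets, labs)
  out <- crossprod(M)
  storage.mode(out) <- "integer"
  class(out) <- c("cooccurrence_matrix", class(out))
  out
}

#' Write a co-occurrence matrix as CSV
#' @param m A [cooccurrence()] matrix.
#' @param path Output path.
#' @export
write_cooccurrence <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
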