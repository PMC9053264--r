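# Internal helpers: seeded evaluation, permutations, token hashing.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, code) {
  code <- substitute(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval(code, envir = parent.frame())
}

# All permutations of 1..k as a k! x k integer matrix (k small).
all_permutations <- function(k) {
  k <- as.integer(k)
  if (k <= 0L) abort("`k` must be a positive integer.")
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out[[i]] <- cbind(rep(i, nrow(sub)),
                      matrix(rest[sub], nrow = nrow(sub)))
  }
  res <- do.call(rbind, out)
  storage.mode(res) <- "integer"
  res
}

# Draw `n` permutations of 1..k, without replacement while n <= k!.
# Uses the current RNG stream; callers wrap in with_seed().
sample_permutations <- function(k, n, warn_replace = TRUE) {
  k <- as.integer(k)
  if (k == 0L) abort("cannot permute zero fields")
  n_distinct <- factorial(k)
  if (k <= 6L) {
    perms <- all_permutations(k)
    if (n <= n_distinct) {
      idx <- if (nrow(perms) == 1L) rep(1L, n) else sample(nrow(perms), n)
      return(perms[idx, , drop = FALSE])
    }
    if (warn_replace) {
      warn(sprintf(
        "requested %d views but only %d distinct field orders exist; sampling with replacement",
        n, n_distinct))
    }
    return(perms[sample(nrow(perms), n, replace = TRUE), , drop = FALSE])
  }
  # k! is large: independent draws collide with negligible probability
  out <- matrix(0L, n, k)
  seen <- character(0)
  for (i in seq_len(n)) {
    for (try in 1:20) {
      p <- sample.int(k)
      key <- paste(p, collapse = ",")
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    out[i, ] <- p
  }
  out
}

# Deterministic polynomial rolling hash of a token into 1..buckets.
hash_one <- function(tok, buckets) {
  h <- 0
  for (c in utf8ToInt(tok)) h <- (h * 31 + c) %% 2147483647
  as.integer(h %% buckets) + 1L
}

hash_tokens <- function(tokens, buckets) {
  vapply(tokens, hash_one, integer(1), buckets = buckets, USE.NAMES = FALSE)
}

# Case-folded, punctuation-stripped word tokens; the unit used both by the
# feature-hashing encoder and by word-knockout interpretability.
tokenize_words <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  toks <- strsplit(trimws(x), " +")
  lapply(toks, function(t) t[nzchar(t)])
}

# clamp helper for probabilities / logs
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == as.integer(x) && x >= 1
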