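# Synopsis corpus data model, text cleaning, serialization and on-disk IO.
#
# A corpus is a tibble with one row per case:
#   case_id    character, unique
#   fields     list of named character vectors (field name -> description),
#              order significant for storage but not for meaning
#   labels     list of character vectors (gold semantic labels), or NULL
#              elements for unlabeled cases
#   provenance optional character source tag

#' Build a synopsis corpus tibble
#'
#' Constructs and validates the canonical corpus representation used across
#' the package: one row per case with `case_id`, a `fields` list-column of
#' named character vectors (field name to description), an optional `labels`
#' list-column of character vectors, and an optional `provenance` column.
#'
#' @param case_id Character vector of unique case identifiers.
#' @param fields List of named character vectors, one per case. Field names
#'   must be unique within a case.
#' @param labels Optional list of character label vectors (gold labels); use
#'   `NULL` elements for unlabeled cases.
#' @param provenance Optional character vector of free-text source tags.
#' @return A tibble of class `synoptic_corpus`.
#' @export
corpus_tbl <- function(case_id, fields, labels = NULL, provenance = NULL) {
  out <- tibble(case_id = as.character(case_id), fields = fields)
  if (!is.null(labels)) out$labels <- labels
  if (!is.null(provenance)) out$provenance <- as.character(provenance)
  as_corpus(out)
}

#' Validate a data frame as a synopsis corpus
#'
#' @param x A data frame with at least `case_id` and `fields` columns.
#' @return `x` as a validated `synoptic_corpus` tibble.
#' @export
as_corpus <- function(x) {
  x <- as_tibble(x)
  if (!all(c("case_id", "fields") %in% names(x))) {
    abort("a corpus needs `case_id` and `fields` columns")
  }
  if (anyNA(x$case_id) || any(!nzchar(x$case_id))) {
    abort("every case needs a non-empty `case_id`")
  }
  if (anyDuplicated(x$case_id)) {
    dup <- unique(x$case_id[duplicated(x$case_id)])
    abort(paste0("duplicate case_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad <- vapply(x$fields, function(f) {
    is.null(names(f)) || any(!nzchar(names(f))) || anyDuplicated(names(f)) > 0
  }, logical(1))
  if (any(bad)) {
    abort(paste0("fields of case ", x$case_id[which(bad)[1]],
                 " need unique, non-empty names"))
  }
  if (!"labels" %in% names(x)) x$labels <- vector("list", nrow(x))
  class(x) <- unique(c("synoptic_corpus", class(x)))
  x
}

#' Drop gold labels from a corpus
#'
#' Returns the same cases with an all-`NULL` `labels` column, e.g. to form an
#' unlabeled pool for active learning.
#'
#' @param corpus A corpus tibble.
#' @return The corpus with labels removed.
#' @export
strip_labels <- function(corpus) {
  corpus <- as_corpus(corpus)
  corpus$labels <- vector("list", nrow(corpus))
  corpus
}

labeled_cases <- function(corpus) {
  corpus[!vapply(corpus$labels, is.null, logical(1)), , drop = FALSE]
}

#' Count labeled cases per label
#'
#' @param corpus A corpus tibble with gold labels.
#' @param vocab Optional [label_vocabulary()]; when given, labels with zero
#'   cases are included with `n = 0`.
#' @return A tibble with columns `label` and `n`.
#' @export
label_counts <- function(corpus, vocab = NULL) {
  corpus <- as_corpus(corpus)
  labs <- unlist(corpus$labels, use.names = FALSE)
  tab <- table(labs)
  all_labels <- if (is.null(vocab)) sort(names(tab)) else vocab_labels(vocab)
  n <- as.integer(tab[all_labels])
  n[is.na(n)] <- 0L
  tibble(label = all_labels, n = n)
}

# ---- label vocabulary -------------------------------------------------------

#' Create a label vocabulary
#'
#' An ordered set of unique semantic label names with a version counter that
#' increments whenever labels are appended. The index of an existing label
#' never changes; new labels are only ever appended, so fitted models can
#' detect vocabulary drift.
#'
#' @param labels Character vector of unique label names.
#' @param version Positive integer version, incremented by [add_labels()].
#' @return An object of class `label_vocabulary`.
#' @export
label_vocabulary <- function(labels = character(), version = 1L) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) abort("vocabulary labels must be unique")
  structure(list(labels = labels, version = as.integer(version)),
            class = "label_vocabulary")
}

#' @export
print.label_vocabulary <- function(x, ...) {
  cat("<label_vocabulary> v", x$version, ": ", length(x$labels), " labels\n",
      sep = "")
  if (length(x$labels)) cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.label_vocabulary <- function(x) length(x$labels)

#' Extract the ordered label names of a vocabulary
#' @param vocab A `label_vocabulary` or plain character vector.
#' @return Character vector of label names.
#' @export
vocab_labels <- function(vocab) {
  if (inherits(vocab, "label_vocabulary")) vocab$labels else as.character(vocab)
}

#' Append new labels to a vocabulary
#'
#' Unknown labels are appended in the order given; existing labels keep their
#' index. The version increments only when at least one label was added.
#'
#' @param vocab A [label_vocabulary()].
#' @param new Character vector of candidate label names.
#' @return The updated vocabulary.
#' @export
add_labels <- function(vocab, new) {
  stopifnot(inherits(vocab, "label_vocabulary"))
  fresh <- setdiff(unique(as.character(new)), vocab$labels)
  if (!length(fresh)) return(vocab)
  label_vocabulary(c(vocab$labels, fresh), version = vocab$version + 1L)
}

#' Read / write a vocabulary file (JSON list of names, order significant)
#' @param path File path.
#' @rdname vocabulary_io
#' @export
read_vocabulary <- function(path) {
  label_vocabulary(jsonlite::fromJSON(path))
}

#' @param vocab A [label_vocabulary()].
#' @rdname vocabulary_io
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(jsonlite::toJSON(vocab_labels(vocab)), path)
  invisible(path)
}

# ---- label-set validation ---------------------------------------------------

#' Validate a gold label set against the exclusivity rule
#'
#' A designated exclusive label (by default `"normal"`) may co-occur only with
#' its designated exception partner (by default `"iron_deficiency"`): a case
#' is either normal (possibly with the exception label) or carries abnormal
#' labels, never both. The rule applies to gold annotations, not predictions.
#'
#' @param labels Character vector of labels for one case.
#' @param exclusive The exclusive label name.
#' @param exception The one label allowed to accompany it.
#' @return `TRUE` invisibly; aborts on violation or an empty set.
#' @export
validate_label_set <- function(labels, exclusive = "normal",
                               exception = "iron_deficiency") {
  if (!length(labels)) abort("a labeled case needs at least one label")
  if (exclusive %in% labels) {
    extra <- setdiff(labels, c(exclusive, exception))
    if (length(extra)) {
      abort(paste0("'", exclusive, "' may only co-occur with '", exception,
                   "', found: ", paste(extra, collapse = ", ")))
    }
  }
  invisible(TRUE)
}

# ---- text cleaning ----------------------------------------------------------

#' Default removable-noise patterns
#'
#' Ordered regular expressions (case-insensitive) for boilerplate commonly
#' appended to synopsis text: signature blocks, transcription disclaimers,
#' reporting-system stamps and accession numbers. The clinical systems these
#' emulate do not publish their formats, so the defaults match the noise
#' templates injected by [generate_corpus()]; supply your own list for real
#' exports.
#'
#' @return Character vector of regular expressions, applied in order.
#' @export
default_noise_patterns <- function() {
  c(signature  = "\\[\\s*signed:[^]]*\\]",
    dictation  = "dictated but not read",
    system     = "reported via the \\w+ reporting system",
    accession  = "accession no\\.? [a-z0-9-]+")
}

#' Clean synopsis text
#'
#' Removes every configured noise pattern in order, collapses internal
#' whitespace runs to single spaces and trims the ends. Idempotent: cleaning
#' twice equals cleaning once. Empty input yields empty output.
#'
#' @param raw Character vector of raw text.
#' @param noise_patterns Ordered character vector of regular expressions to
#'   delete (matched case-insensitively).
#' @return Cleaned character vector.
#' @export
clean_text <- function(raw, noise_patterns = default_noise_patterns()) {
  out <- raw
  for (p in noise_patterns) {
    out <- gsub(p, " ", out, ignore.case = TRUE, perl = TRUE)
  }
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

#' Clean every field description in a corpus
#'
#' @param corpus A corpus tibble.
#' @param noise_patterns Passed to [clean_text()].
#' @return The corpus with cleaned descriptions.
#' @export
clean_corpus <- function(corpus, noise_patterns = default_noise_patterns()) {
  corpus <- as_corpus(corpus)
  corpus$fields <- lapply(corpus$fields, function(f) {
    cleaned <- clean_text(unname(f), noise_patterns)
    names(cleaned) <- names(f)
    cleaned
  })
  corpus
}

# ---- serialization ----------------------------------------------------------

#' Serialize a synopsis to a single text string
#'
#' Concatenates `"field: description"` segments in the given field order,
#' joined by `"; "`. The multiset of whitespace-delimited tokens is identical
#' across all permutations, which is what makes field-order shuffling a
#' label-preserving augmentation.
#'
#' @param fields Named character vector (field name -> description).
#' @param order Integer permutation of `seq_along(fields)`; defaults to the
#'   stored order.
#' @return A single string.
#' @export
serialize_synopsis <- function(fields, order = seq_along(fields)) {
  k <- length(fields)
  order <- as.integer(order)
  if (length(order) != k || !setequal(order, seq_len(k))) {
    abort("`order` must be a permutation of the field indices")
  }
  if (k == 0L) return("")
  paste0(names(fields)[order], ": ", unname(fields)[order], collapse = "; ")
}

# Serialize every case of a corpus in canonical (stored) field order.
serialize_corpus <- function(corpus) {
  vapply(corpus$fields, serialize_synopsis, character(1))
}

# ---- on-disk formats --------------------------------------------------------

#' Read a synopsis corpus from disk
#'
#' Supported formats: `jsonl` (one JSON record per line with `case_id`,
#' `fields` as `[name, description]` pairs, and optional `labels`), `wide`
#' delimited (header row, `case_id` plus one column per field, optional
#' pipe-separated `labels` column), and `long` delimited (`case_id`,
#' `field_name`, `description`). Delimited files may be comma- or
#' tab-separated (chosen by extension, `.tsv` = tab). All text is
#' Unicode-normalized to NFC on read for stable tokenization.
#'
#' @param path Input file path.
#' @param format One of `"jsonl"`, `"wide"`, `"long"`.
#' @param vocab Optional [label_vocabulary()]; with `strict = TRUE`, labels
#'   outside it raise an error.
#' @param strict Enforce the vocabulary on read.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path, format = c("jsonl", "wide", "long"),
                        vocab = NULL, strict = FALSE) {
  format <- match.arg(format)
  corpus <- switch(format,
    jsonl = read_corpus_jsonl(path),
    wide  = read_corpus_wide(path),
    long  = read_corpus_long(path))
  corpus$fields <- lapply(corpus$fields, function(f) {
    v <- stringi::stri_trans_nfc(unname(f))
    names(v) <- stringi::stri_trans_nfc(names(f))
    v
  })
  if (strict && !is.null(vocab)) {
    unknown <- setdiff(unlist(corpus$labels), vocab_labels(vocab))
    if (length(unknown)) {
      abort(paste0("labels not in vocabulary: ",
                   paste(unique(unknown), collapse = ", ")))
    }
  }
  as_corpus(corpus)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  ids <- vapply(recs, function(r) {
    if (is.null(r$case_id)) abort("jsonl record without case_id")
    as.character(r$case_id)
  }, character(1))
  fields <- lapply(recs, function(r) {
    pairs <- r$fields
    v <- vapply(pairs, function(p) as.character(p[[2]]), character(1))
    names(v) <- vapply(pairs, function(p) as.character(p[[1]]), character(1))
    v
  })
  labels <- lapply(recs, function(r) {
    if (is.null(r$labels)) NULL else as.character(unlist(r$labels))
  })
  corpus_tbl(ids, fields, labels)
}

read_corpus_wide <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", encoding = "UTF-8")
  if (!"case_id" %in% names(df)) abort("wide corpus needs a case_id column")
  has_labels <- "labels" %in% names(df)
  field_cols <- setdiff(names(df), c("case_id", "labels", "provenance"))
  fields <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.character(df[i, field_cols])
    names(v) <- field_cols
    v
  })
  labels <- if (has_labels) {
    lapply(df$labels, function(s) {
      if (is.na(s) || !nzchar(s)) NULL else strsplit(s, "|", fixed = TRUE)[[1]]
    })
  } else NULL
  corpus_tbl(df$case_id, fields, labels)
}

read_corpus_long <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", encoding = "UTF-8")
  need <- c("case_id", "field_name", "description")
  if (!all(need %in% names(df))) {
    abort("long corpus needs case_id, field_name, description columns")
  }
  ids <- unique(df$case_id)
  fields <- lapply(ids, function(id) {
    sub <- df[df$case_id == id, , drop = FALSE]
    if (anyDuplicated(sub$field_name)) {
      abort(paste0("duplicate field_name for case ", id))
    }
    setNames(sub$description, sub$field_name)
  })
  corpus_tbl(ids, fields)
}

#' Write a synopsis corpus to disk
#'
#' Inverse of [read_corpus()]; `write_corpus()` then [read_corpus()]
#' reproduces the corpus exactly (including field order and labels for
#' `jsonl`), and the jsonl round trip is byte-stable.
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @param format One of `"jsonl"`, `"wide"`, `"long"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "wide", "long")) {
  format <- match.arg(format)
  corpus <- as_corpus(corpus)
  switch(format,
    jsonl = {
      lines <- vapply(seq_len(nrow(corpus)), function(i) {
        f <- corpus$fields[[i]]
        rec <- list(
          case_id = corpus$case_id[i],
          fields = lapply(seq_along(f), function(j) c(names(f)[j], f[[j]])))
        if (!is.null(corpus$labels[[i]])) rec$labels <- I(corpus$labels[[i]])
        as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
      }, character(1))
      writeLines(lines, path, useBytes = TRUE)
    },
    wide = {
      sep <- if (grepl("\\.tsv$", path)) "\t" else ","
      field_cols <- unique(unlist(lapply(corpus$fields, names)))
      df <- data.frame(case_id = corpus$case_id, stringsAsFactors = FALSE)
      for (fc in field_cols) {
        df[[fc]] <- vapply(corpus$fields, function(f) {
          if (fc %in% names(f)) f[[fc]] else ""
        }, character(1))
      }
      if (any(!vapply(corpus$labels, is.null, logical(1)))) {
        df$labels <- vapply(corpus$labels, function(l) {
          paste(l, collapse = "|")
        }, character(1))
      }
      write.csv2_sep(df, path, sep)
    },
    long = {
      sep <- if (grepl("\\.tsv$", path)) "\t" else ","
      df <- tidyr::unnest_longer(
        tibble(case_id = corpus$case_id,
               field_name = lapply(corpus$fields, names),
               description = lapply(corpus$fields, unname)),
        c("field_name", "description"))
      write.csv2_sep(as.data.frame(df), path, sep)
    })
  invisible(path)
}

write.csv2_sep <- function(df, path, sep) {
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double",
                     fileEncoding = "UTF-8")
}
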