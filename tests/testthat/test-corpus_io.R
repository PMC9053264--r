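test_that("clean_text removes configured noise, squashes whitespace, and is idempotent", {
  expect_identical(clean_text(""), "")
  raw <- "Cellularity:  normal   \n\n[signed: Dr. X]"
  expect_identical(clean_text(raw), "Cellularity: normal")
  plain <- "Cellularity: normal marrow"
  expect_identical(clean_text(plain), plain)
  # idempotence over generated noisy descriptions
  gen <- generate_corpus(generator_config(n_cases = 40, seed = 3,
                                          noise_rate = 1))
  for (f in gen$corpus$fields) {
    once <- clean_text(unname(f))
    expect_identical(clean_text(once), once)
  }
  # the generator's injected noise is removed by the default patterns
  cleaned <- clean_corpus(gen$corpus)
  for (i in seq_len(nrow(cleaned))) {
    txt <- serialize_synopsis(cleaned$fields[[i]])
    expect_false(grepl("signed|copath|accession|dictated", txt))
  }
})

test_that("serialize_synopsis respects the given order and rejects non-permutations", {
  f <- c(A = "x", B = "y")
  expect_identical(serialize_synopsis(f), "A: x; B: y")
  expect_identical(serialize_synopsis(f, c(2, 1)), "B: y; A: x")
  tok <- function(s) sort(strsplit(s, "[ ;:]+")[[1]])
  expect_identical(tok(serialize_synopsis(f)), tok(serialize_synopsis(f, 2:1)))
  expect_error(serialize_synopsis(f, c(1, 1)), "permutation")
  expect_error(serialize_synopsis(f, 1L), "permutation")
})

test_that("a 3-field synopsis has exactly 3! distinct serializations with one token multiset", {
  f <- c(A = "x", B = "y", C = "z")
  perms <- synoptic:::all_permutations(3)
  texts <- apply(perms, 1, function(p) serialize_synopsis(f, p))
  expect_length(unique(texts), 6L)
  tok <- function(s) sort(strsplit(s, "[ ;:]+")[[1]])
  mats <- unique(lapply(texts, tok))
  expect_length(mats, 1L)
})

test_that("token multiset is permutation-invariant for up to 5 fields", {
  for (k in 2:5) {
    f <- stats::setNames(paste("desc", seq_len(k), "words"),
                         paste0("f", seq_len(k)))
    perms <- synoptic:::all_permutations(k)
    tok <- function(s) sort(strsplit(s, "[ ;:]+")[[1]])
    mats <- unique(apply(perms, 1, function(p) {
      paste(tok(serialize_synopsis(f, p)), collapse = "|")
    }))
    expect_length(mats, 1L)
  }
})

test_that("corpus round-trips exactly through jsonl, and byte-stably", {
  corpus <- toy_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path, "jsonl")
  back <- read_corpus(path, "jsonl")
  expect_identical(back$case_id, corpus$case_id)
  expect_identical(back$fields, corpus$fields)
  expect_identical(back$labels, corpus$labels)
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(back, path2, "jsonl")
  expect_identical(readLines(path), readLines(path2))
})

test_that("wide and long delimited encodings load to the same synopses", {
  corpus <- toy_corpus()
  wide <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, wide, "wide")
  from_wide <- read_corpus(wide, "wide")
  long <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, long, "long")
  from_long <- read_corpus(long, "long")
  expect_identical(from_wide$fields, corpus$fields)
  expect_identical(from_long$fields, corpus$fields)
  expect_identical(from_wide$labels, corpus$labels)
})

test_that("malformed corpora are rejected", {
  expect_error(
    corpus_tbl(c("a", "a"),
               list(c(f = "x"), c(f = "y"))),
    "duplicate case_id")
  expect_error(
    corpus_tbl("a", list(c("x", "y"))),  # unnamed fields
    "unique, non-empty names")
  corpus <- toy_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path, "jsonl")
  vocab <- label_vocabulary(c("normal", "iron"))
  expect_error(read_corpus(path, "jsonl", vocab = vocab, strict = TRUE),
               "not in vocabulary")
})

test_that("vocabulary appends keep indices stable and bump the version", {
  v <- label_vocabulary(c("a", "b"))
  v2 <- add_labels(v, c("b", "c"))
  expect_identical(vocab_labels(v2), c("a", "b", "c"))
  expect_identical(v2$version, 2L)
  expect_identical(add_labels(v2, "a")$version, 2L)
  expect_error(label_vocabulary(c("a", "a")), "unique")
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(v2, path)
  expect_identical(vocab_labels(read_vocabulary(path)), c("a", "b", "c"))
})

test_that("the exclusive-label rule admits only the exception partner", {
  expect_true(validate_label_set(c("normal", "iron_deficiency")))
  expect_true(validate_label_set("normal"))
  expect_true(validate_label_set(c("aml", "mds"),
                                 exclusive = "normal"))
  expect_error(validate_label_set(c("normal", "aml")), "co-occur")
  expect_error(validate_label_set(character()), "at least one label")
})
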