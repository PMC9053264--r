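# Synthetic synopsis generator with planted ground truth, and the default
# labelling oracle built on it. Emulates the structure of bone marrow
# aspirate synopses: ordered field:description records, an imbalanced
# multi-label distribution with co-occurring pairs, a "normal" label that is
# mutually exclusive of abnormal labels (iron deficiency excepted), planted
# label keywords, and injected reporting-system noise.

#' Default label table for the synthetic generator
#'
#' Twelve semantic labels with an imbalanced (long-tailed) prior, one unique
#' planted keyword per label, and the synopsis field that keyword is written
#' into. The tail makes roughly four labels rare (expected count below 20 in
#' a 500-case sample), which is what exercises rare-label enrichment.
#'
#' @return A tibble with columns `label`, `prior`, `keyword`, `field`.
#' @export
default_generator_labels <- function() {
  tibble(
    label = c("normal", "hypercellular", "erythroid_hyperplasia",
              "myelodysplastic_syndrome", "acute_myeloid_leukemia",
              "hypocellular", "iron_deficiency", "chronic_myeloid_leukemia",
              "megakaryocyte_atypia", "acute_lymphoblastic_leukemia",
              "lymphoproliferative_disorder", "plasma_cell_neoplasm"),
    prior = c(0.345, 0.16, 0.12, 0.09, 0.07, 0.06, 0.05, 0.04,
              0.03, 0.015, 0.01, 0.01),
    keyword = c("unremarkable", "hypercellular", "erythroblastosis",
                "dysplasia", "myeloblasts", "hypocellular", "sideropenia",
                "basophilia", "micromegakaryocytes", "lymphoblasts",
                "lymphocytosis", "plasmacytosis"),
    field = c("cellularity", "cellularity", "erythropoiesis",
              "granulopoiesis", "granulopoiesis", "cellularity",
              "erythropoiesis", "granulopoiesis", "megakaryocytes",
              "lymphocytes", "lymphocytes", "lymphocytes"))
}

#' Default synopsis field schema
#'
#' Six fields echoing aspirate synopsis sections, each with a background
#' vocabulary of benign reporting words (disjoint from every planted
#' keyword).
#'
#' @return Named list of character vectors.
#' @export
default_field_schema <- function() {
  list(
    cellularity = c("marrow", "particles", "adequate", "spicules",
                    "trilineage", "haematopoiesis", "maturation", "preserved",
                    "estimate", "cellular"),
    erythropoiesis = c("erythroid", "series", "normoblastic", "maturation",
                       "present", "proportion", "forms", "orderly",
                       "sequential", "nuclear"),
    granulopoiesis = c("myeloid", "series", "granulocytic", "maturation",
                       "progressive", "orderly", "neutrophils", "precursors",
                       "present", "ratio"),
    megakaryocytes = c("megakaryocytes", "number", "morphology", "lobated",
                       "nuclei", "present", "adequate", "clusters", "budding",
                       "platelet"),
    lymphocytes = c("lymphoid", "cells", "small", "mature", "scattered",
                    "proportion", "polyclonal", "interstitial", "present",
                    "population"),
    comment = c("overall", "findings", "correlate", "clinical", "flow",
                "cytometry", "cytogenetics", "pending", "recommended",
                "review"))
}

#' Default elevated label co-occurrence pairs
#'
#' Directional: `prob` is the probability that a case whose primary label is
#' `a` also carries `b`. The plasma-cell-neoplasm entries give the default
#' hidden label several abnormal companions, mirroring how an undescribed
#' entity surfaces while experts review cases sampled for other rare labels.
#'
#' @return Tibble with columns `a`, `b`, `prob`.
#' @export
default_cooccur_pairs <- function() {
  tibble(
    a = c("acute_myeloid_leukemia", "myelodysplastic_syndrome",
          "lymphoproliferative_disorder", "plasma_cell_neoplasm",
          "plasma_cell_neoplasm", "plasma_cell_neoplasm"),
    b = c("hypercellular", "megakaryocyte_atypia", "plasma_cell_neoplasm",
          "erythroid_hyperplasia", "hypocellular", "megakaryocyte_atypia"),
    prob = c(0.5, 0.4, 0.3, 0.5, 0.5, 0.5))
}

#' Configuration for the synthetic synopsis generator
#'
#' @param n_cases Number of cases to generate.
#' @param seed Integer seed; the generated corpus is byte-identical for a
#'   fixed seed and config.
#' @param labels Label table as in [default_generator_labels()]; priors are
#'   the primary-label multinomial and must sum to 1 (renormalized with a
#'   warning otherwise); keywords must be unique and absent from every
#'   background vocabulary.
#' @param field_schema Named list of per-field background vocabularies.
#' @param cooccur_pairs Label pairs with elevated joint probability.
#' @param exclusive_label The "normal" analogue: co-occurs only with
#'   `exception_label`.
#' @param exception_label The one label allowed alongside the exclusive one.
#' @param exception_rate Probability the exception label joins an
#'   exclusive-label case.
#' @param extra_rate Probability an abnormal case gains one extra uniformly
#'   chosen abnormal label.
#' @param hidden_labels Labels withheld from the oracle's initial random
#'   sample; they are only revealed when a case carrying them is queried,
#'   emulating label discovery during active learning.
#' @param noise_rate Probability a case has one noise template (signature,
#'   dictation disclaimer, reporting-system stamp, accession number) appended
#'   to its comment field.
#' @param keyword_dropout Probability a planted keyword is omitted ("hard
#'   mode"); 0 keeps keyword determinism strict so that a case contains label
#'   k's keyword iff k is in its gold label set.
#' @param tokens_per_field Integer range (min, max) of background tokens per
#'   field description.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 500, seed = 1,
                             labels = default_generator_labels(),
                             field_schema = default_field_schema(),
                             cooccur_pairs = default_cooccur_pairs(),
                             exclusive_label = "normal",
                             exception_label = "iron_deficiency",
                             exception_rate = 0.3,
                             extra_rate = 0.15,
                             hidden_labels = "plasma_cell_neoplasm",
                             noise_rate = 0.3,
                             keyword_dropout = 0,
                             tokens_per_field = c(3L, 6L)) {
  labels <- as_tibble(labels)
  stopifnot(all(c("label", "prior", "keyword", "field") %in% names(labels)))
  if (anyDuplicated(labels$label)) abort("generator labels must be unique")
  if (anyDuplicated(labels$keyword)) abort("planted keywords must be unique")
  if (abs(sum(labels$prior) - 1) > 1e-8) {
    warn("label priors do not sum to 1; renormalizing")
    labels$prior <- labels$prior / sum(labels$prior)
  }
  if (!all(labels$field %in% names(field_schema))) {
    abort("every keyword field must exist in the field schema")
  }
  bg <- unlist(field_schema, use.names = FALSE)
  if (any(labels$keyword %in% bg)) {
    abort("planted keywords must not occur in background vocabularies")
  }
  if (!all(hidden_labels %in% labels$label)) {
    abort("hidden_labels must be a subset of the generator labels")
  }
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed), labels = labels,
    field_schema = field_schema, cooccur_pairs = as_tibble(cooccur_pairs),
    exclusive_label = exclusive_label, exception_label = exception_label,
    exception_rate = exception_rate, extra_rate = extra_rate,
    hidden_labels = as.character(hidden_labels), noise_rate = noise_rate,
    keyword_dropout = keyword_dropout,
    tokens_per_field = as.integer(tokens_per_field)),
    class = "generator_config")
}

noise_templates <- function() {
  c("[signed: dr %s md]",
    "dictated but not read",
    "reported via the copath reporting system",
    "accession no. bm-%04d")
}

draw_label_set <- function(cfg) {
  lt <- cfg$labels
  primary <- sample(lt$label, 1L, prob = lt$prior)
  if (primary == cfg$exclusive_label) {
    labs <- primary
    if (runif(1) < cfg$exception_rate) labs <- c(labs, cfg$exception_label)
    return(labs)
  }
  labs <- primary
  cp <- cfg$cooccur_pairs
  for (r in seq_len(nrow(cp))) {
    if (cp$a[r] != primary) next
    partner <- cp$b[r]
    if (partner != cfg$exclusive_label && !(partner %in% labs) &&
        runif(1) < cp$prob[r]) {
      labs <- c(labs, partner)
    }
  }
  if (runif(1) < cfg$extra_rate) {
    extras <- setdiff(lt$label, c(labs, cfg$exclusive_label))
    if (length(extras)) labs <- c(labs, sample(extras, 1L))
  }
  labs
}

#' Generate a synthetic synopsis corpus with known ground truth
#'
#' Each case draws a label set from the configured prior (with co-occurrence
#' and exclusivity rules), composes field descriptions from background
#' vocabulary, plants every drawn label's keyword into its designated field,
#' and may append one noise template to the comment field. Noise never
#' deletes planted keywords. Deterministic for a fixed config.
#'
#' @param cfg A [generator_config()].
#' @return A list with elements `corpus` (a labeled corpus tibble) and
#'   `truth` (gold labels, keyword map, hidden-label list, and the config).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_cases
  schema <- cfg$field_schema
  field_names <- names(schema)
  lt <- cfg$labels
  surnames <- c("hale", "osei", "tanaka", "moreau", "lindqvist")

  with_seed(cfg$seed, {
    case_id <- sprintf("case_%05d", seq_len(n))
    labels <- lapply(seq_len(n), function(i) draw_label_set(cfg))
    fields <- lapply(seq_len(n), function(i) {
      labs <- labels[[i]]
      kw <- lt[lt$label %in% labs, , drop = FALSE]
      desc <- vapply(field_names, function(fn) {
        k <- sample(seq(cfg$tokens_per_field[1], cfg$tokens_per_field[2]), 1L)
        words <- sample(schema[[fn]], k, replace = TRUE)
        planted <- kw$keyword[kw$field == fn]
        if (cfg$keyword_dropout > 0 && length(planted)) {
          planted <- planted[runif(length(planted)) >= cfg$keyword_dropout]
        }
        for (w in planted) {
          pos <- sample(length(words) + 1L, 1L)
          words <- append(words, w, after = pos - 1L)
        }
        paste(words, collapse = " ")
      }, character(1))
      if (runif(1) < cfg$noise_rate) {
        tpl <- sample(noise_templates(), 1L)
        noise <- if (grepl("%s", tpl)) sprintf(tpl, sample(surnames, 1L))
                 else if (grepl("%04d", tpl)) sprintf(tpl, sample(9999L, 1L))
                 else tpl
        desc[["comment"]] <- paste(desc[["comment"]], noise)
      }
      desc
    })
    corpus <- corpus_tbl(case_id, fields, labels)
  })

  truth <- list(
    gold = setNames(labels, case_id),
    keywords = setNames(lt$keyword, lt$label),
    keyword_fields = setNames(lt$field, lt$label),
    hidden_labels = cfg$hidden_labels,
    exclusive_label = cfg$exclusive_label,
    exception_label = cfg$exception_label,
    config = cfg)
  list(corpus = corpus, truth = truth)
}

#' Synthetic labelling oracle
#'
#' Wraps a generated corpus as a labelling oracle for the active-learning
#' loop: `query(case_ids)` returns the true label sets, and the first time a
#' case carrying a hidden label is queried, that label's name is emitted once
#' through the `new_labels` attribute — emulating experts discovering a new
#' semantic label while reviewing sampled cases. `initial_sample(n, seed)`
#' draws the seed set from cases carrying no hidden label, so hidden labels
#' are only reachable through sampling.
#'
#' @param generated The list returned by [generate_corpus()], or a labeled
#'   corpus tibble.
#' @param hidden_labels Hidden labels (defaults to the generator's).
#' @return An object of class `label_oracle` with elements `query`,
#'   `initial_sample`, and `name`.
#' @export
synthetic_oracle <- function(generated, hidden_labels = NULL) {
  corpus <- if (is.data.frame(generated)) as_corpus(generated)
            else as_corpus(generated$corpus)
  if (is.null(hidden_labels)) {
    hidden_labels <- if (is.data.frame(generated)) character()
                     else generated$truth$hidden_labels
  }
  gold <- setNames(corpus$labels, corpus$case_id)
  env <- new.env(parent = emptyenv())
  env$revealed <- character()

  query <- function(case_ids) {
    case_ids <- as.character(case_ids)
    unknown <- setdiff(case_ids, names(gold))
    if (length(unknown)) {
      abort(paste0("unknown case ids: ", paste(head(unknown, 5), collapse = ", ")))
    }
    ans <- tibble(case_id = case_ids, labels = unname(gold[case_ids]))
    seen <- unique(unlist(ans$labels))
    newly <- setdiff(intersect(seen, hidden_labels), env$revealed)
    env$revealed <- union(env$revealed, newly)
    attr(ans, "new_labels") <- newly
    ans
  }

  initial_sample <- function(n, seed = 1, from = NULL) {
    eligible <- corpus$case_id[!vapply(corpus$labels, function(l) {
      any(l %in% hidden_labels)
    }, logical(1))]
    if (!is.null(from)) eligible <- intersect(eligible, from)
    with_seed(seed, sample(eligible, min(n, length(eligible))))
  }

  structure(list(query = query, initial_sample = initial_sample,
                 name = "synthetic", hidden_labels = hidden_labels),
            class = "label_oracle")
}

#' File-based labelling oracle for human-in-the-loop deployments
#'
#' `query(case_ids)` writes `candidates.csv` (one case id per row) into `dir`
#' and expects a reviewer to supply `verified.csv` with columns `case_id` and
#' `labels` (pipe-separated). If the verified file is missing or incomplete
#' the query aborts with instructions, so an active-learning run can be
#' resumed after each annotation round.
#'
#' @param dir Directory used to exchange candidate and verified CSV files.
#' @return A `label_oracle`.
#' @export
file_oracle <- function(dir) {
  query <- function(case_ids) {
    cand_path <- file.path(dir, "candidates.csv")
    ver_path <- file.path(dir, "verified.csv")
    utils::write.table(data.frame(case_id = case_ids), cand_path,
                       sep = ",", row.names = FALSE)
    if (!file.exists(ver_path)) {
      abort(paste0("awaiting review: label the cases in ", cand_path,
                   " and save them to ", ver_path))
    }
    df <- read.csv(ver_path, colClasses = "character")
    missing <- setdiff(case_ids, df$case_id)
    if (length(missing)) {
      abort(paste0(ver_path, " lacks verdicts for: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    df <- df[match(case_ids, df$case_id), , drop = FALSE]
    ans <- tibble(case_id = df$case_id,
                  labels = strsplit(df$labels, "|", fixed = TRUE))
    attr(ans, "new_labels") <- character()
    ans
  }
  structure(list(query = query, initial_sample = NULL, name = "file"),
            class = "label_oracle")
}
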