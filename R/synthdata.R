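# Seeded synthetic fixtures: a layered random DAG ontology, a corpus whose
# documents draw words from term-specific signal vocabularies plus
# background noise, a skewed annotations-per-document distribution, and a
# held-out query set disjoint from the knowledge base.

#' Synthetic-benchmark configuration
#'
#' The defaults state a small but realistic benchmark world: a 50-term DAG
#' of depth 4; 500 knowledge-base documents plus 100 held-out queries;
#' disjoint 20-word signal vocabularies per term over a 200-word background
#' vocabulary; half of each abstract's words are noise
#' (`noise_rate = 0.5`); and an annotations-per-document distribution
#' skewed like real literature-derived GO annotation sets, where 39% of
#' documents carry a single gold term and essentially all carry at most 10.
#' Titles are mostly signal — the publication title carries the strongest
#' annotation signal — while abstracts mix signal and noise.
#'
#' @param seed integer seed; the single source of randomness.
#' @param n_terms total DAG size including the root.
#' @param depth number of layers below the root.
#' @param n_pubs knowledge-base corpus size.
#' @param n_test held-out query count.
#' @param words_per_term signal vocabulary size per term (disjoint across
#'   terms).
#' @param noise_vocab background vocabulary size.
#' @param noise_rate fraction of abstract words drawn from the background
#'   vocabulary.
#' @param ann_per_pub_probs probability of 1, 2, ... gold terms per
#'   document.
#' @param ref_prob probability that a document cites any given earlier
#'   knowledge-base document sharing its primary term.
#' @param year_range inclusive publication-year range.
#' @param title_words,abstract_words document lengths in words.
#' @return an object of class `gota_synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_terms = 50L,
                         depth = 4L,
                         n_pubs = 500L,
                         n_test = 100L,
                         words_per_term = 20L,
                         noise_vocab = 200L,
                         noise_rate = 0.5,
                         ann_per_pub_probs = c(0.39, 0.22, 0.13, 0.09, 0.06,
                                               0.04, 0.03, 0.02, 0.013, 0.007),
                         ref_prob = 0.3,
                         year_range = c(1980L, 2015L),
                         title_words = 8L,
                         abstract_words = 60L) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              depth = as.integer(depth), n_pubs = as.integer(n_pubs),
              n_test = as.integer(n_test),
              words_per_term = as.integer(words_per_term),
              noise_vocab = as.integer(noise_vocab),
              noise_rate = noise_rate,
              ann_per_pub_probs = ann_per_pub_probs / sum(ann_per_pub_probs),
              ref_prob = ref_prob,
              year_range = as.integer(year_range),
              title_words = as.integer(title_words),
              abstract_words = as.integer(abstract_words))
  stopifnot(cfg$n_terms >= 3L, cfg$depth >= 1L, cfg$n_pubs >= 1L,
            cfg$n_test >= 0L, cfg$words_per_term >= 3L,
            cfg$noise_rate >= 0, cfg$noise_rate <= 1,
            cfg$ref_prob >= 0, cfg$ref_prob <= 1,
            all(cfg$ann_per_pub_probs >= 0))
  structure(cfg, class = "gota_synth_config")
}

.make_ontology <- function(terms) {
  parents <- lapply(terms, `[[`, "parents")
  onto <- structure(
    list(terms = terms, parents = parents,
         roots = names(terms)[vapply(parents, length, integer(1)) == 0L]),
    class = "gota_ontology"
  )
  onto$anc <- .ancestor_closures(onto)
  onto
}

#' Generate a synthetic benchmark
#'
#' Builds, fully reproducibly from the configured seed:
#' \enumerate{
#'   \item a layered random DAG: one root, the remaining terms spread
#'     evenly over `depth` layers, each term drawing 1-2 parents from the
#'     layer above;
#'   \item a disjoint signal vocabulary per term (the term's name and
#'     synonym are phrases over its own vocabulary, so name matching and
#'     stem coverage are informative);
#'   \item documents whose gold term count follows
#'     `ann_per_pub_probs`, with titles composed mostly (90%) of signal
#'     words of their gold terms, abstracts mixing signal and noise at
#'     `noise_rate`, a uniform year, and citations preferentially to
#'     knowledge-base documents sharing the document's primary (first)
#'     gold term;
#'   \item a held-out test set of `n_test` documents disjoint from the
#'     knowledge base.
#' }
#'
#' @param config a [synth_config()].
#' @return an object of class `gota_synth`: list with `onto`
#'   (`gota_ontology`), `kb` (`gota_kb`), `test_pubs` (list of
#'   publications), `test_gold` (`gota_annotations`) and `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "gota_synth_config"))
  set.seed(config$seed)

  # ---- DAG ----
  n_inner <- config$n_terms - 1L
  layer_sizes <- diff(floor(seq(0, n_inner, length.out = config$depth + 1L)))
  if (any(layer_sizes == 0L)) stop("too few terms for the requested depth")
  ids <- sprintf("GO:%07d", seq_len(config$n_terms))
  layers <- list(ids[1L])
  next_id <- 2L
  for (ls in layer_sizes) {
    layers[[length(layers) + 1L]] <- ids[seq(next_id, next_id + ls - 1L)]
    next_id <- next_id + ls
  }

  # ---- vocabularies ----
  vocab <- lapply(seq_len(config$n_terms), function(i) {
    sprintf("gene%03dx%02d", i, seq_len(config$words_per_term))
  })
  names(vocab) <- ids
  noise_words <- sprintf("filler%04d", seq_len(config$noise_vocab))

  terms <- list()
  for (li in seq_along(layers)) {
    for (id in layers[[li]]) {
      i <- match(id, ids)
      v <- vocab[[id]]
      parents <- if (li == 1L) character(0) else {
        above <- layers[[li - 1L]]
        sample(above, size = min(length(above), sample(1:2, 1L)))
      }
      terms[[id]] <- list(
        id = id,
        name = paste(v[1L], v[2L]),
        synonyms = paste(v[3L], v[4L]),
        namespace = "BP",
        parents = sort(parents),
        description = paste(v[5:min(8L, length(v))], collapse = " "),
        obsolete = FALSE
      )
    }
  }
  onto <- .make_ontology(terms)

  # ---- documents ----
  n_total <- config$n_pubs + config$n_test
  assignable <- ids[-1L]  # root is never a gold annotation
  max_ann <- min(length(config$ann_per_pub_probs), length(assignable))
  pmids <- sprintf("%07d", 1000000L + seq_len(n_total))
  years <- sample(seq(config$year_range[1L], config$year_range[2L]),
                  n_total, replace = TRUE)
  gold_sets <- vector("list", n_total)
  titles <- character(n_total)
  abstracts <- character(n_total)
  for (d in seq_len(n_total)) {
    n_ann <- sample.int(max_ann, 1L,
                        prob = config$ann_per_pub_probs[seq_len(max_ann)])
    gold <- sample(assignable, n_ann)
    gold_sets[[d]] <- sort(gold)
    signal_pool <- unlist(vocab[gold], use.names = FALSE)
    title_sig <- stats::runif(config$title_words) < 0.9
    titles[d] <- paste(ifelse(
      title_sig,
      sample(signal_pool, config$title_words, replace = TRUE),
      sample(noise_words, config$title_words, replace = TRUE)
    ), collapse = " ")
    abs_noise <- stats::runif(config$abstract_words) < config$noise_rate
    abstracts[d] <- paste(ifelse(
      abs_noise,
      sample(noise_words, config$abstract_words, replace = TRUE),
      sample(signal_pool, config$abstract_words, replace = TRUE)
    ), collapse = " ")
  }

  # ---- citations: preferentially to same-primary-term KB documents ----
  primary <- vapply(gold_sets, `[[`, character(1), 1L)
  refs <- vector("list", n_total)
  kb_range <- seq_len(config$n_pubs)
  for (d in seq_len(n_total)) {
    peers <- kb_range[primary[kb_range] == primary[d] & kb_range != d]
    if (length(peers) == 0L) { refs[[d]] <- character(0); next }
    cited <- peers[stats::runif(length(peers)) < config$ref_prob]
    refs[[d]] <- pmids[cited]
  }

  pubs <- lapply(seq_len(n_total), function(d) {
    publication(pmids[d], title = titles[d], abstract = abstracts[d],
                references = refs[[d]], year = years[d])
  })
  names(gold_sets) <- pmids

  kb <- build_kb(pubs[kb_range],
                 annotation_set(gold_sets[kb_range]),
                 onto, quiet = TRUE)
  test_idx <- setdiff(seq_len(n_total), kb_range)
  structure(
    list(onto = onto, kb = kb,
         test_pubs = stats::setNames(pubs[test_idx], pmids[test_idx]),
         test_gold = if (length(test_idx)) {
           annotation_set(gold_sets[test_idx])
         } else NULL,
         config = config),
    class = "gota_synth"
  )
}

#' @export
print.gota_synth <- function(x, ...) {
  cat("gota synthetic benchmark: ", length(x$onto$terms), " terms, ",
      length(x$kb$publications), " KB documents, ",
      length(x$test_pubs), " held-out queries (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic benchmark to fixture files
#'
#' Emits exactly the plain-text formats the package readers accept, so the
#' bundle round-trips: `ontology.obo` ([parse_obo()]),
#' `kb_corpus.jsonl` / `test_corpus.jsonl` ([read_corpus_jsonl()]) and
#' `kb_annotations.tsv` / `test_annotations.tsv`
#' ([read_annotations()] with `format = "tsv"`).
#'
#' @param bundle a `gota_synth`.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir, force = FALSE) {
  stopifnot(inherits(bundle, "gota_synth"))
  if (length(bundle$kb$publications) == 0L) stop("empty bundle")
  .prepare_dir(dir, force)
  writeLines(.obo_lines(bundle$onto), file.path(dir, "ontology.obo"))
  .write_corpus_jsonl(bundle$kb$publications, file.path(dir, "kb_corpus.jsonl"))
  .write_annotations_tsv(bundle$kb$gold, file.path(dir, "kb_annotations.tsv"))
  if (length(bundle$test_pubs)) {
    .write_corpus_jsonl(bundle$test_pubs, file.path(dir, "test_corpus.jsonl"))
    .write_annotations_tsv(bundle$test_gold,
                           file.path(dir, "test_annotations.tsv"))
  }
  invisible(dir)
}

.obo_lines <- function(onto) {
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    out <- c(out, "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$namespace)) {
      full <- switch(t$namespace, BP = "biological_process",
                     MF = "molecular_function", CC = "cellular_component",
                     t$namespace)
      out <- c(out, paste0("namespace: ", full))
    }
    if (nzchar(t$description)) {
      out <- c(out, paste0("def: \"", t$description, "\" []"))
    }
    for (s in t$synonyms) {
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (p in t$parents) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  out
}

.write_corpus_jsonl <- function(pubs, path) {
  lines <- vapply(pubs, function(p) {
    jsonlite::toJSON(
      list(pmid = p$pmid, title = p$title, abstract = p$abstract,
           year = if (is.na(p$year)) NULL else p$year,
           references = as.list(p$references)),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }, character(1))
  writeLines(lines, path)
}

.write_annotations_tsv <- function(gold, path) {
  lines <- unlist(lapply(names(gold), function(pmid) {
    paste(pmid, gold[[pmid]], sep = "\t")
  }))
  writeLines(lines, path)
}

#' Read a fixture directory back into a benchmark bundle
#'
#' @param dir directory written by [write_fixture()].
#' @return a `gota_synth`-shaped list (without `config`).
#' @export
read_fixture <- function(dir) {
  onto <- parse_obo(file.path(dir, "ontology.obo"))
  pubs <- read_corpus_jsonl(file.path(dir, "kb_corpus.jsonl"))
  gold <- read_annotations(file.path(dir, "kb_annotations.tsv"), "tsv")
  kb <- build_kb(pubs, gold, onto, quiet = TRUE)
  out <- list(onto = onto, kb = kb, test_pubs = NULL, test_gold = NULL)
  test_path <- file.path(dir, "test_corpus.jsonl")
  if (file.exists(test_path)) {
    tp <- read_corpus_jsonl(test_path)
    out$test_pubs <- stats::setNames(tp, vapply(tp, `[[`, character(1), "pmid"))
    out$test_gold <- read_annotations(file.path(dir, "test_annotations.tsv"),
                                      "tsv")
  }
  structure(out, class = "gota_synth")
}
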