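# Text preprocessing: tokenization (stopword filtering + Porter stemming),
# idf fitting over the joint publication/term document pool, tf-idf and
# reference vectors, cosine similarity.
#
# Weighted vectors are plain named numeric vectors: names are feature ids
# (stems, or cited pmids for reference vectors), values are non-negative
# weights, explicit zeros dropped.

.stopword_cache <- new.env(parent = emptyenv())

#' Default English stopword list
#'
#' A standard English stopword list (articles, prepositions, auxiliaries,
#' common adverbs such as "actually" and "after") shipped with the package.
#' Any user-supplied character vector can be passed to [tokenize()] and
#' [fit_idf()] instead.
#'
#' @return character vector of lowercase stopwords.
#' @export
gota_stopwords <- function() {
  if (is.null(.stopword_cache$words)) {
    path <- system.file("extdata", "stopwords_en.txt", package = "gota")
    .stopword_cache$words <- readLines(path, warn = FALSE)
  }
  .stopword_cache$words
}

#' Tokenize text into stems
#'
#' Lowercases, splits on non-alphanumeric characters (so punctuation is
#' discarded but mixed tokens like `p53` survive intact), drops
#' single-character tokens and stopwords, and Porter-stems the remainder.
#' Order is preserved and duplicates are kept: the output feeds term
#' frequencies.
#'
#' @param text character scalar (or vector, concatenated with spaces).
#' @param stopwords character vector of words to drop (before stemming).
#' @return character vector of stems (possibly empty).
#' @examples
#' tokenize("Binding of p53")  # "of" is a stopword
#' @export
tokenize <- function(text, stopwords = gota_stopwords()) {
  text <- tolower(paste(text, collapse = " "))
  toks <- strsplit(text, "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) > 1L]
  toks <- toks[!(toks %in% stopwords)]
  if (length(toks) == 0L) return(character(0))
  porter_stem(toks)
}

#' Fit the inverse-document-frequency model
#'
#' The document pool for word idf is the union of (a) every knowledge-base
#' publication's title + abstract and (b) every ontology term's name +
#' synonyms + description, each counted once:
#' `idf(w) = ln(N / df(w))` with `N` = number of publications + number of
#' terms and `df(w)` the number of pool documents containing `w`. A word
#' occurring in every document therefore gets idf 0.
#'
#' Reference idf uses only publications that carry a bibliography:
#' `idf_ref(r) = ln(B / c(r))` with `B` = number of publications with at
#' least one reference and `c(r)` = number of publications citing `r`.
#'
#' @param kb a `gota_kb` knowledge base.
#' @param onto a `gota_ontology`.
#' @param stopwords stopword list used for all tokenization under this
#'   model.
#' @return an object of class `gota_idf`: list with `word_idf`, `ref_idf`
#'   (named numeric vectors), `n_docs_and_terms`, `n_docs_with_bibliography`
#'   and `stopwords`.
#' @export
fit_idf <- function(kb, onto, stopwords = gota_stopwords()) {
  stopifnot(inherits(kb, "gota_kb"), inherits(onto, "gota_ontology"))
  pubs <- kb$publications
  if (length(pubs) == 0L) stop("empty knowledge base")

  df <- new.env(parent = emptyenv(), hash = TRUE)
  bump <- function(stems) {
    for (s in unique(stems)) {
      cur <- df[[s]]
      df[[s]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  for (p in pubs) bump(tokenize(paste(p$title, p$abstract), stopwords))
  for (t in onto$terms) {
    bump(tokenize(paste(t$name, paste(t$synonyms, collapse = " "),
                        t$description), stopwords))
  }
  n_units <- length(pubs) + length(onto$terms)
  words <- sort(ls(df))
  counts <- vapply(words, function(w) df[[w]], integer(1))
  word_idf <- stats::setNames(log(n_units / counts), words)

  with_bib <- Filter(function(p) length(p$references) > 0L, pubs)
  b <- length(with_bib)
  ref_idf <- stats::setNames(numeric(0), character(0))
  if (b > 0L) {
    cited <- table(unlist(lapply(with_bib, function(p) unique(p$references))))
    ref_idf <- stats::setNames(log(b / as.integer(cited)), names(cited))
    ref_idf <- ref_idf[sort(names(ref_idf))]
  }
  structure(
    list(word_idf = word_idf, ref_idf = ref_idf,
         n_docs_and_terms = n_units, n_docs_with_bibliography = b,
         stopwords = stopwords),
    class = "gota_idf"
  )
}

#' @export
print.gota_idf <- function(x, ...) {
  cat("gota idf model:", length(x$word_idf), "stems over",
      x$n_docs_and_terms, "documents+terms;",
      length(x$ref_idf), "reference pmids over",
      x$n_docs_with_bibliography, "bibliographies\n")
  invisible(x)
}

#' Build a tf-idf weighted vector from text
#'
#' `weight(w) = tf(w, text) * idf(w)`, where the term frequency denominator
#' is the total token count after stopword removal and stemming. Tokens
#' outside the fitted vocabulary cannot match any knowledge-base dimension
#' and are omitted (they still count in the tf denominator).
#'
#' @param text character scalar.
#' @param model a `gota_idf` model.
#' @return named numeric vector (a weighted vector; possibly empty).
#' @export
tfidf_vector <- function(text, model) {
  stopifnot(inherits(model, "gota_idf"))
  toks <- tokenize(text, model$stopwords)
  if (length(toks) == 0L) return(stats::setNames(numeric(0), character(0)))
  counts <- table(toks)
  idf <- model$word_idf[names(counts)]
  keep <- !is.na(idf)
  w <- (as.numeric(counts[keep]) / length(toks)) * unname(idf[keep])
  v <- stats::setNames(w, names(counts)[keep])
  v[v > 0]
}

#' Build a weighted reference vector
#'
#' Each distinct cited pmid known to the model contributes its `idf_ref`
#' weight; pmids never cited in the knowledge base are omitted.
#'
#' @param references character vector of cited pmids.
#' @param model a `gota_idf` model.
#' @return named numeric vector (possibly empty).
#' @export
ref_vector <- function(references, model) {
  stopifnot(inherits(model, "gota_idf"))
  refs <- unique(as.character(references))
  idf <- model$ref_idf[refs]
  keep <- !is.na(idf)
  v <- stats::setNames(unname(idf[keep]), refs[keep])
  v[v > 0]
}

#' Cosine similarity between two weighted vectors
#'
#' `x . y / (||x|| ||y||)`, always in `[0, 1]` because all weights are
#' non-negative; defined as 0 when either vector is empty or zero.
#'
#' @param x,y named numeric vectors.
#' @return similarity in `[0, 1]`.
#' @export
cosine <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  common <- intersect(names(x), names(y))
  if (length(common) == 0L) return(0)
  min(sum(x[common] * y[common]) / (nx * ny), 1)
}
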