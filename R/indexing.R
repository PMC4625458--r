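# Indexing: per-publication and per-term feature bundles, the assembled
# searchable index (sparse matrices for the k-NN scan), and a plain-text
# serialized form.

#' Index a publication
#'
#' Builds the four query/target features of a publication: `W` (tf-idf bag
#' of words over title + abstract), `T` (over the title only), `R`
#' (weighted reference vector) and `Y` (year). The `W` vector must be
#' non-empty — a publication whose text reduces to nothing in-vocabulary
#' cannot be compared with anything.
#'
#' @param p a [publication()].
#' @param model a `gota_idf` model.
#' @return an object of class `gota_pub_index`: list with `pmid`, `W`, `T`,
#'   `R` (named numeric vectors) and `Y` (integer or `NA`).
#' @export
index_publication <- function(p, model) {
  stopifnot(inherits(p, "gota_publication"))
  w <- tfidf_vector(paste(p$title, p$abstract), model)
  if (length(w) == 0L) {
    stop("publication ", p$pmid, " has no usable in-vocabulary text")
  }
  structure(
    list(pmid = p$pmid,
         W = w,
         T = tfidf_vector(p$title, model),
         R = ref_vector(p$references, model),
         Y = p$year),
    class = "gota_pub_index"
  )
}

#' Index an ontology term
#'
#' The text bag of words `W` of a term covers its name, synonyms and
#' description plus the title and abstract of every knowledge-base
#' publication *directly* annotated with the term (no ancestor propagation
#' at indexing time; set `propagate = TRUE` to change that). `T` covers
#' name and synonyms only. `Y` is the mean publication year of the
#' annotating publications, rounded to the nearest year, or `NA` if the
#' term annotates no publication. `phrases` holds the lowercased,
#' whitespace-normalized name and synonyms (for literal phrase matching)
#' and `title_stems` the stem set of name + synonyms (for stem coverage).
#'
#' @param term a term record from a `gota_ontology`.
#' @param kb a `gota_kb`.
#' @param model a `gota_idf` model.
#' @param propagate logical; also include publications annotated with
#'   descendant terms (default `FALSE`).
#' @param onto required when `propagate = TRUE`.
#' @return an object of class `gota_term_index`.
#' @export
index_term <- function(term, kb, model, propagate = FALSE, onto = NULL) {
  if (!nzchar(term$name)) stop("term ", term$id, " has an empty name")
  anns <- unclass(kb$gold)
  direct <- names(anns)[vapply(anns, function(x) term$id %in% x, logical(1))]
  if (propagate) {
    stopifnot(inherits(onto, "gota_ontology"))
    direct <- names(anns)[vapply(anns, function(x) {
      term$id %in% ancestors(onto, x)
    }, logical(1))]
  }
  own_text <- paste(term$name, paste(term$synonyms, collapse = " "),
                    term$description)
  pub_text <- vapply(kb$publications[direct], function(p) {
    paste(p$title, p$abstract)
  }, character(1))
  years <- vapply(kb$publications[direct], function(p) {
    if (is.na(p$year)) NA_real_ else as.numeric(p$year)
  }, numeric(1))
  years <- years[!is.na(years)]

  phrases <- .normalize_phrase(c(term$name, term$synonyms))
  title_stems <- unique(tokenize(paste(term$name,
                                       paste(term$synonyms, collapse = " ")),
                                 model$stopwords))
  w <- tfidf_vector(paste(c(own_text, pub_text), collapse = " "), model)
  tt <- tfidf_vector(paste(term$name, paste(term$synonyms, collapse = " ")),
                     model)
  structure(
    list(id = term$id,
         W = w, T = tt,
         Y = if (length(years)) as.integer(round(mean(years))) else NA_integer_,
         phrases = phrases[nzchar(phrases)],
         title_stems = title_stems),
    class = "gota_term_index"
  )
}

.normalize_phrase <- function(x) {
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Build the searchable index over a knowledge base
#'
#' Fits the idf model, indexes every publication and every ontology term,
#' and assembles row-normalized sparse matrices of the publication `W`, `T`
#' and `R` vectors so that ranking a query against the whole knowledge base
#' is a handful of sparse matrix-vector products.
#'
#' @param kb a `gota_kb`.
#' @param onto a `gota_ontology`.
#' @param stopwords stopword list (see [gota_stopwords()]).
#' @param verbose print progress messages.
#' @return an object of class `gota_index`: list with `model`, `pubs`
#'   (named list of `gota_pub_index`), `terms` (named list of
#'   `gota_term_index`), `gold`, `onto` and internal matrices.
#' @export
build_index <- function(kb, onto, stopwords = gota_stopwords(),
                        verbose = FALSE) {
  stopifnot(inherits(kb, "gota_kb"), inherits(onto, "gota_ontology"))
  if (verbose) message("fitting idf model over ", length(kb$publications),
                       " publications and ", length(onto$terms), " terms")
  model <- fit_idf(kb, onto, stopwords)
  pubs <- lapply(kb$publications, index_publication, model = model)
  if (verbose) message("indexing ", length(onto$terms), " terms")
  terms <- lapply(onto$terms, index_term, kb = kb, model = model)
  idx <- structure(
    list(model = model, pubs = pubs, terms = terms,
         gold = kb$gold, onto = onto),
    class = "gota_index"
  )
  idx$mat <- .pub_matrices(idx)
  idx
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

.sparse_from_vectors <- function(vectors, features) {
  # Rows: one per list element (L2-normalized); columns: feature ids.
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (r in seq_along(vectors)) {
    v <- .unit(vectors[[r]])
    if (length(v) == 0L) next
    cols <- match(names(v), features)
    keep <- !is.na(cols)
    i <- c(i, rep.int(r, sum(keep)))
    j <- c(j, cols[keep])
    x <- c(x, unname(v[keep]))
  }
  Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(vectors), length(features)),
    dimnames = list(names(vectors), features)
  )
}

.pub_matrices <- function(idx) {
  vocab <- names(idx$model$word_idf)
  refids <- names(idx$model$ref_idf)
  pubs <- idx$pubs
  list(
    W = .sparse_from_vectors(lapply(pubs, `[[`, "W"), vocab),
    T = .sparse_from_vectors(lapply(pubs, `[[`, "T"), vocab),
    R = .sparse_from_vectors(lapply(pubs, `[[`, "R"), refids),
    years = vapply(pubs, function(p) {
      if (is.na(p$Y)) NA_real_ else as.numeric(p$Y)
    }, numeric(1))
  )
}

#' @export
print.gota_index <- function(x, ...) {
  cat("gota index:", length(x$pubs), "publications,",
      length(x$terms), "terms,",
      length(x$model$word_idf), "stem features,",
      length(x$model$ref_idf), "reference features\n")
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

INDEX_SCHEMA_VERSION <- "1"

.vec_to_json <- function(v) {
  if (length(v) == 0L) return(list())
  as.list(stats::setNames(as.numeric(v), names(v)))
}

#' Write a searchable index to disk
#'
#' Serializes a `gota_index` into a directory of plain-text files (schema
#' version 1): `meta.json` (version + counts), `idf.tsv` and `ref_idf.tsv`
#' (the fitted idf tables), `stopwords.txt`, `pubs.json` and `terms.json`
#' (per-record weighted vectors, full precision), `gold.tsv` and
#' `ontology.json`. Serialization is deterministic: identical indexes
#' produce byte-identical directories.
#'
#' @param idx a `gota_index`.
#' @param dir output directory; created if absent.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_index <- function(idx, dir, force = FALSE) {
  stopifnot(inherits(idx, "gota_index"))
  .prepare_dir(dir, force)
  meta <- list(schema = INDEX_SCHEMA_VERSION,
               n_pubs = length(idx$pubs), n_terms = length(idx$terms),
               n_docs_and_terms = idx$model$n_docs_and_terms,
               n_docs_with_bibliography = idx$model$n_docs_with_bibliography)
  .write_json(meta, file.path(dir, "meta.json"))
  .write_idf_tsv(idx$model$word_idf, file.path(dir, "idf.tsv"))
  .write_idf_tsv(idx$model$ref_idf, file.path(dir, "ref_idf.tsv"))
  writeLines(idx$model$stopwords, file.path(dir, "stopwords.txt"))

  pubs <- lapply(idx$pubs, function(p) {
    list(pmid = p$pmid, W = .vec_to_json(p$W), T = .vec_to_json(p$T),
         R = .vec_to_json(p$R),
         Y = if (is.na(p$Y)) NULL else p$Y)
  })
  .write_json(unname(pubs), file.path(dir, "pubs.json"))
  terms <- lapply(idx$terms, function(t) {
    list(id = t$id, W = .vec_to_json(t$W), T = .vec_to_json(t$T),
         Y = if (is.na(t$Y)) NULL else t$Y,
         phrases = as.list(t$phrases), title_stems = as.list(t$title_stems))
  })
  .write_json(unname(terms), file.path(dir, "terms.json"))

  gold_lines <- unlist(lapply(names(idx$gold), function(pmid) {
    paste(pmid, idx$gold[[pmid]], sep = "\t")
  }))
  writeLines(gold_lines, file.path(dir, "gold.tsv"))

  onto <- lapply(idx$onto$terms, function(t) {
    list(id = t$id, name = t$name, synonyms = as.list(t$synonyms),
         namespace = if (is.na(t$namespace)) NULL else t$namespace,
         parents = as.list(t$parents), description = t$description)
  })
  .write_json(unname(onto), file.path(dir, "ontology.json"))
  invisible(dir)
}

.prepare_dir <- function(dir, force) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("directory ", dir, " exists and is non-empty (use force = TRUE)")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
}

.write_json <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
}

.write_idf_tsv <- function(v, path) {
  lines <- if (length(v)) {
    paste(names(v), formatC(unname(v), format = "g", digits = 17), sep = "\t")
  } else {
    character(0)
  }
  writeLines(lines, path)
}

.read_idf_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(as.numeric(vapply(fields, `[[`, character(1), 2L)),
                  vapply(fields, `[[`, character(1), 1L))
}

.json_to_vec <- function(lst) {
  if (length(lst) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(vapply(lst, as.numeric, numeric(1)), names(lst))
}

#' Read a serialized index
#'
#' Inverse of [write_index()]. The schema version in `meta.json` must
#' match the version this package writes.
#'
#' @param dir directory written by [write_index()].
#' @return a `gota_index`.
#' @export
read_index <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  if (!identical(as.character(meta$schema), INDEX_SCHEMA_VERSION)) {
    stop("unsupported index schema version: ", meta$schema)
  }
  model <- structure(
    list(word_idf = .read_idf_tsv(file.path(dir, "idf.tsv")),
         ref_idf = .read_idf_tsv(file.path(dir, "ref_idf.tsv")),
         n_docs_and_terms = meta$n_docs_and_terms,
         n_docs_with_bibliography = meta$n_docs_with_bibliography,
         stopwords = readLines(file.path(dir, "stopwords.txt"), warn = FALSE)),
    class = "gota_idf"
  )
  raw_pubs <- jsonlite::fromJSON(file.path(dir, "pubs.json"),
                                 simplifyVector = FALSE)
  pubs <- lapply(raw_pubs, function(p) {
    structure(
      list(pmid = p$pmid, W = .json_to_vec(p$W), T = .json_to_vec(p$T),
           R = .json_to_vec(p$R),
           Y = if (is.null(p$Y)) NA_integer_ else as.integer(p$Y)),
      class = "gota_pub_index"
    )
  })
  names(pubs) <- vapply(pubs, `[[`, character(1), "pmid")
  raw_terms <- jsonlite::fromJSON(file.path(dir, "terms.json"),
                                  simplifyVector = FALSE)
  terms <- lapply(raw_terms, function(t) {
    structure(
      list(id = t$id, W = .json_to_vec(t$W), T = .json_to_vec(t$T),
           Y = if (is.null(t$Y)) NA_integer_ else as.integer(t$Y),
           phrases = unlist(t$phrases),
           title_stems = as.character(unlist(t$title_stems))),
      class = "gota_term_index"
    )
  })
  names(terms) <- vapply(terms, `[[`, character(1), "id")

  gold_lines <- readLines(file.path(dir, "gold.tsv"), warn = FALSE)
  pairs <- .parse_tsv_pairs(gold_lines)
  gold <- annotation_set(split(pairs$term, pairs$pmid))

  raw_onto <- jsonlite::fromJSON(file.path(dir, "ontology.json"),
                                 simplifyVector = FALSE)
  oterms <- lapply(raw_onto, function(t) {
    list(id = t$id, name = t$name, synonyms = as.character(unlist(t$synonyms)),
         namespace = if (is.null(t$namespace)) NA_character_ else t$namespace,
         parents = as.character(unlist(t$parents)),
         description = t$description, obsolete = FALSE)
  })
  names(oterms) <- vapply(oterms, `[[`, character(1), "id")
  parents <- lapply(oterms, `[[`, "parents")
  onto <- structure(
    list(terms = oterms, parents = parents,
         roots = names(oterms)[vapply(parents, length, integer(1)) == 0L]),
    class = "gota_ontology"
  )
  onto$anc <- .ancestor_closures(onto)

  idx <- structure(
    list(model = model, pubs = pubs, terms = terms, gold = gold, onto = onto),
    class = "gota_index"
  )
  idx$mat <- .pub_matrices(idx)
  idx
}
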