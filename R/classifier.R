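# The classifier: combine the publication-centric transfer score with the
# term-centric re-weighting into a single ranked prediction, plus the two
# naive frequency/information-content baselines.

#' Index a query
#'
#' Builds the query-side feature bundle either from a structured
#' [publication()] record (all four features available) or from raw
#' unstructured text (text bag of words only). For raw text the classifier
#' does not know whether the input relates to a title or an abstract, so
#' the title bag of words is left empty unless `is_title = TRUE`.
#'
#' @param query a [publication()] or a character scalar of raw text.
#' @param idx a `gota_index`.
#' @param is_title for raw-text queries: treat the text as a title.
#' @return a `gota_pub_index` with an extra `raw_text` field.
#' @export
index_query <- function(query, idx, is_title = FALSE) {
  stopifnot(inherits(idx, "gota_index"))
  if (inherits(query, "gota_publication")) {
    q <- index_publication(query, idx$model)
    q$raw_text <- paste(query$title, query$abstract)
    return(q)
  }
  text <- paste(as.character(query), collapse = " ")
  w <- tfidf_vector(text, idx$model)
  if (length(w) == 0L) stop("no usable text: query has no in-vocabulary token")
  structure(
    list(pmid = NULL, W = w,
         T = if (is_title) w else stats::setNames(numeric(0), character(0)),
         R = stats::setNames(numeric(0), character(0)),
         Y = NA_integer_, raw_text = text),
    class = "gota_pub_index"
  )
}

.new_prediction <- function(query_id, terms, scores) {
  ord <- order(-scores, terms)
  structure(
    list(query_id = query_id,
         ranked = data.frame(term = terms[ord], score = unname(scores[ord]),
                             stringsAsFactors = FALSE)),
    class = "gota_prediction"
  )
}

#' @export
print.gota_prediction <- function(x, n = 10L, ...) {
  cat("gota prediction for query", x$query_id, "-",
      nrow(x$ranked), "term(s)\n")
  print(utils::head(x$ranked, n))
  invisible(x)
}

#' Predict GO terms for a query
#'
#' The combined score of a candidate term is
#' `Phi(q, t) = Phi_P(q, t) * Phi_T(q, t)`: the k-NN transfer score from
#' the top-K most similar knowledge-base publications, re-weighted by the
#' direct query-term comparison. Candidates are the terms with a positive
#' transfer score — only terms annotated to some knowledge-base
#' publication can be predicted (set `all_terms = TRUE` to score the whole
#' vocabulary for diagnostics; terms without transfer score then rank by
#' `Phi_T` alone and sort after all transferred candidates).
#'
#' @param query a [publication()] or raw text (see [index_query()]).
#' @param idx a `gota_index`.
#' @param params a [gota_params()].
#' @param top_n number of ranked terms to return (default 10, the
#'   evaluation focus).
#' @param exclude_self leave-one-out: exclude the knowledge-base
#'   publication with the query's own pmid from the neighbour ranking.
#' @param is_title for raw-text queries, treat the text as a title.
#' @param all_terms score every ontology term instead of the transferred
#'   candidates only.
#' @return a `gota_prediction`: `query_id` plus a data frame `ranked` with
#'   columns `term` and `score`, sorted by descending score (ties by
#'   ascending accession), truncated to `top_n` rows.
#' @export
gota_predict <- function(query, idx, params = gota_params(), top_n = 10L,
                         exclude_self = TRUE, is_title = FALSE,
                         all_terms = FALSE) {
  q <- index_query(query, idx, is_title = is_title)
  neighbors <- rank_neighbors(q, idx, params, exclude_self = exclude_self)
  phi_p <- score_terms_pubcentric(neighbors, idx$gold)
  cand <- names(phi_p)
  if (all_terms) cand <- names(idx$terms)
  if (length(cand) == 0L) {
    return(.new_prediction(if (is.null(q$pmid)) "query" else q$pmid,
                           character(0), numeric(0)))
  }
  phi_t <- vapply(idx$terms[cand], function(t) {
    phi_T(q, q$raw_text, t, params)
  }, numeric(1))
  base <- phi_p[cand]
  base[is.na(base)] <- 0
  # Phi_P is 0 for non-candidate terms; give them an epsilon-free ranking
  # below every transferred candidate by using Phi_T alone.
  score <- ifelse(base > 0, base * phi_t, 0)
  if (all_terms) {
    floor_score <- phi_t / (max(phi_t) + 1)
    score <- ifelse(base > 0, score, floor_score)
  }
  keep <- score > 0
  pred <- .new_prediction(if (is.null(q$pmid)) "query" else q$pmid,
                          names(score)[keep], score[keep])
  pred$ranked <- utils::head(pred$ranked, top_n)
  pred
}

#' Frequency baseline (RandFR)
#'
#' Ranks GO terms by their direct-annotation frequency in the knowledge
#' base, ties broken by ascending accession. The same prediction is
#' returned for every query.
#'
#' @param kb_gold a `gota_annotations` (e.g. `idx$gold`).
#' @param top_n number of ranked terms to return.
#' @return a `gota_prediction` with `query_id = "RandFR"`.
#' @export
baseline_randfr <- function(kb_gold, top_n = 10L) {
  stopifnot(inherits(kb_gold, "gota_annotations"))
  counts <- table(unlist(kb_gold, use.names = FALSE))
  pred <- .new_prediction("RandFR", names(counts), as.numeric(counts))
  pred$ranked <- utils::head(pred$ranked, top_n)
  pred
}

#' Information-content baseline (RandIC)
#'
#' Ranks each GO term by its average information-theoretic precision over
#' all knowledge-base publications: the mean, over publications `p`, of
#' the best Lin similarity between the term and the leaf reduction of
#' `p`'s gold annotation set. A term annotated to every publication scores
#' 1; a root (ic 0) scores 0. The same prediction is returned for every
#' query.
#'
#' @param kb_gold a `gota_annotations`.
#' @param onto a `gota_ontology`.
#' @param ict a `gota_ic` table.
#' @param terms candidate accessions to rank (default: all ontology terms).
#' @param top_n number of ranked terms to return.
#' @return a `gota_prediction` with `query_id = "RandIC"`.
#' @export
baseline_randic <- function(kb_gold, onto, ict, terms = names(onto$terms),
                            top_n = 10L) {
  stopifnot(inherits(kb_gold, "gota_annotations"))
  leaf_sets <- lapply(kb_gold, function(x) leaves(onto, x))
  gold_leaves <- unique(unlist(leaf_sets, use.names = FALSE))
  # Lin similarity of every candidate against every observed gold leaf.
  sim <- matrix(0, length(terms), length(gold_leaves),
                dimnames = list(terms, gold_leaves))
  for (t in terms) {
    for (g in gold_leaves) sim[t, g] <- lin(onto, ict, t, g)
  }
  scores <- vapply(terms, function(t) {
    mean(vapply(leaf_sets, function(ls) max(sim[t, ls]), numeric(1)))
  }, numeric(1))
  pred <- .new_prediction("RandIC", terms, scores)
  pred$ranked <- utils::head(pred$ranked, top_n)
  pred
}
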