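# Term-centric score: direct comparison between a query and a GO term,
# used to re-weight the candidate terms proposed by the publication-centric
# k-NN transfer.

#' Query-term comparison features
#'
#' The five similarities in `[0, 1]` between a query and a term:
#' \describe{
#'   \item{g1}{cosine between the text bags of words of query and term;}
#'   \item{g2}{cosine between the title bag of words of the query and the
#'     name bag of words of the term (0 when the query has no
#'     distinguishable title);}
#'   \item{g3}{fraction of the term's name/synonym stems present in the
#'     query's text bag of words;}
#'   \item{g4}{literal occurrence count `c` of the term's full name and
#'     synonyms in the raw query text (case-insensitive, whitespace
#'     normalized, counted before stemming), normalized as `min(c, 4)/4`
#'     — occurrences of distinct synonym phrases are summed;}
#'   \item{g5}{year proximity `(50 - |dY|)/50`, 0 beyond 50 years or when
#'     either year is unknown.}
#' }
#' As for the publication features, any information missing on either side
#' yields a 0 feature, which the product score turns into a neutral factor.
#'
#' @param q a `gota_pub_index` for the query.
#' @param raw_text raw query text (title + abstract, pre-tokenization) used
#'   for literal phrase matching.
#' @param t a `gota_term_index`.
#' @return named numeric vector `c(g1, g2, g3, g4, g5)`.
#' @export
term_features <- function(q, raw_text, t) {
  if (length(t$title_stems) == 0L) {
    stop("term ", t$id, " has no name stems; term index is invalid")
  }
  g3 <- length(intersect(t$title_stems, names(q$W))) / length(t$title_stems)
  c(g1 = cosine(q$W, t$W),
    g2 = cosine(q$T, t$T),
    g3 = g3,
    g4 = .phrase_feature(t$phrases, raw_text),
    g5 = .year_feature(q$Y, t$Y))
}

.phrase_feature <- function(phrases, raw_text) {
  text <- .normalize_phrase(raw_text)
  if (!nzchar(text) || length(phrases) == 0L) return(0)
  cnt <- 0L
  for (ph in phrases) {
    hits <- gregexpr(ph, text, fixed = TRUE)[[1]]
    if (hits[1] != -1L) cnt <- cnt + length(hits)
  }
  min(cnt, 4L) / 4
}

#' Term comparison score
#'
#' `Phi_T(q, t) = prod_i (1 + g_i)^(n_i)`. Always >= 1, with equality
#' exactly when every feature is 0. For unstructured-text queries only
#' `g1`, `g3` and `g4` can be non-zero (no title, no year), so only the
#' corresponding exponents participate — this falls out of the feature
#' definitions, no special-casing.
#'
#' @inheritParams term_features
#' @param params a [gota_params()].
#' @return score >= 1.
#' @export
phi_T <- function(q, raw_text, t, params = gota_params()) {
  g <- term_features(q, raw_text, t)
  prod((1 + g)^params$n)
}
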