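# Publication-centric score: rank knowledge-base publications against a
# query with a product of (1 + feature)^exponent similarities, then transfer
# the gold annotations of the top-K neighbours, weighted by that score.

#' Classifier parameters
#'
#' The exponents act as relative feature weights inside the two product
#' scores: `m` weighs the four publication-comparison features (text,
#' title, references, year), `n` the five query-term features (text, title,
#' name-stem coverage, name occurrence, year). An exponent of 0 switches
#' the feature off. `K` is the number of nearest knowledge-base
#' publications whose annotations are transferred; useful values range
#' from 50 to 300, with the shipped default at the tuned optimum.
#'
#' Defaults are the tuned values `m = (4, 1, 3, 1)`, `n = (4, 1, 2, 1, 1)`,
#' `K = 150`.
#'
#' @param m integer vector of four non-negative exponents.
#' @param n integer vector of five non-negative exponents.
#' @param K number of nearest neighbours (>= 1).
#' @return an object of class `gota_params`.
#' @export
gota_params <- function(m = c(4, 1, 3, 1), n = c(4, 1, 2, 1, 1), K = 150) {
  m <- as.numeric(m); n <- as.numeric(n); K <- as.integer(K)
  stopifnot(length(m) == 4L, length(n) == 5L, K >= 1L,
            all(m >= 0), all(n >= 0))
  if (any(c(m, n) > 4)) {
    warning("exponent(s) above 4 are outside the tuned range")
  }
  structure(list(m = m, n = n, K = K), class = "gota_params")
}

#' @export
print.gota_params <- function(x, ...) {
  cat("gota params: m = (", paste(x$m, collapse = ", "),
      "), n = (", paste(x$n, collapse = ", "), "), K =", x$K, "\n")
  invisible(x)
}

#' Publication-comparison features
#'
#' The four similarities in `[0, 1]` between a query and a target
#' publication: `f1` cosine of the text bags of words, `f2` cosine of the
#' title bags of words, `f3` cosine of the weighted reference vectors, and
#' `f4` the year proximity `(50 - |dY|) / 50`, 0 beyond 50 years or when
#' either year is unknown. Any feature unavailable for the query (no
#' title, no bibliography, no year) is 0 and, through the product form of
#' the score, does not affect the comparison.
#'
#' @param q,p `gota_pub_index` objects.
#' @return named numeric vector `c(f1, f2, f3, f4)`.
#' @export
pub_features <- function(q, p) {
  c(f1 = cosine(q$W, p$W),
    f2 = cosine(q$T, p$T),
    f3 = cosine(q$R, p$R),
    f4 = .year_feature(q$Y, p$Y))
}

.year_feature <- function(y1, y2) {
  if (is.na(y1) || is.na(y2)) return(0)
  d <- abs(as.numeric(y1) - as.numeric(y2))
  if (d > 50) 0 else (50 - d) / 50
}

#' Publication comparison score
#'
#' `phi_P(q, p) = prod_i (1 + f_i)^(m_i)`. Always >= 1; a missing or
#' zero-valued feature contributes a factor of 1.
#'
#' @param q,p `gota_pub_index` objects.
#' @param params a [gota_params()].
#' @return score >= 1.
#' @export
phi_P <- function(q, p, params = gota_params()) {
  f <- pub_features(q, p)
  prod((1 + f)^params$m)
}

#' Rank knowledge-base publications against a query
#'
#' Computes `phi_P` between the query and every indexed publication (as a
#' set of sparse matrix-vector products) and returns the top-K, sorted by
#' descending score with ties broken by ascending pmid. When the query's
#' own pmid is present in the knowledge base it is excluded
#' (leave-one-out), unless `exclude_self = FALSE`.
#'
#' @param q a `gota_pub_index` (see [index_publication()] or
#'   [index_query()]).
#' @param idx a `gota_index`.
#' @param params a [gota_params()].
#' @param exclude_self logical; drop the knowledge-base publication whose
#'   pmid equals the query's.
#' @return data frame with columns `pmid` and `score`, at most `K` rows.
#' @export
rank_neighbors <- function(q, idx, params = gota_params(),
                           exclude_self = TRUE) {
  stopifnot(inherits(idx, "gota_index"))
  if (length(idx$pubs) == 0L) stop("empty knowledge-base index")
  scores <- .phi_P_all(q, idx, params)
  pmids <- names(idx$pubs)
  if (exclude_self && !is.null(q$pmid)) {
    keep <- pmids != q$pmid
    scores <- scores[keep]; pmids <- pmids[keep]
  }
  if (length(pmids) == 0L) stop("no knowledge-base publication to rank")
  ord <- order(-scores, pmids)
  top <- ord[seq_len(min(params$K, length(ord)))]
  data.frame(pmid = pmids[top], score = unname(scores[top]),
             stringsAsFactors = FALSE)
}

.project <- function(v, mat) {
  # Cosine of v against every (already L2-normalized) row of mat.
  if (length(v) == 0L) return(numeric(nrow(mat)))
  u <- .unit(v)
  cols <- match(names(u), colnames(mat))
  keep <- !is.na(cols)
  if (!any(keep)) return(numeric(nrow(mat)))
  out <- as.numeric(mat[, cols[keep], drop = FALSE] %*% unname(u[keep]))
  pmin(out, 1)
}

.phi_P_all <- function(q, idx, params) {
  m <- params$m
  f1 <- .project(q$W, idx$mat$W)
  f2 <- .project(q$T, idx$mat$T)
  f3 <- .project(q$R, idx$mat$R)
  years <- idx$mat$years
  f4 <- if (is.null(q$Y) || is.na(q$Y)) {
    numeric(length(years))
  } else {
    d <- abs(as.numeric(q$Y) - years)
    ifelse(is.na(d) | d > 50, 0, (50 - d) / 50)
  }
  (1 + f1)^m[1] * (1 + f2)^m[2] * (1 + f3)^m[3] * (1 + f4)^m[4]
}

#' Transfer annotations from ranked neighbours
#'
#' `Phi_P(q, t)`: the sum of neighbour scores over the top-K neighbours
#' directly annotated with term `t` (no DAG propagation). Terms annotated
#' to no neighbour are absent from the result, i.e. score 0 — only terms
#' associated to some knowledge-base publication can be selected.
#'
#' @param neighbors data frame from [rank_neighbors()].
#' @param gold a `gota_annotations`.
#' @return named numeric vector of positive term scores.
#' @export
score_terms_pubcentric <- function(neighbors, gold) {
  if (nrow(neighbors) == 0L) stop("no neighbours to transfer annotations from")
  anns <- unclass(gold)[neighbors$pmid]
  lens <- vapply(anns, function(x) if (is.null(x)) 0L else length(x),
                 integer(1))
  if (sum(lens) == 0L) return(stats::setNames(numeric(0), character(0)))
  terms <- unlist(anns, use.names = FALSE)
  w <- rep.int(neighbors$score, lens)
  agg <- tapply(w, terms, sum)
  v <- stats::setNames(as.numeric(agg), names(agg))
  v[sort(names(v))]
}
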