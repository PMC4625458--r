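# Evaluation metrics: reciprocal rank and recall at k (TREC), hierarchical
# precision/recall/F at k (BioCreative), the threshold-swept hierarchical
# F-max (CAFA), and information-theoretic precision/recall built on Lin
# semantic similarity.

.pred_terms <- function(pred) {
  if (inherits(pred, "gota_prediction")) pred$ranked$term else as.character(pred)
}
.pred_scores <- function(pred) {
  if (inherits(pred, "gota_prediction")) pred$ranked$score else attr(pred, "scores")
}

#' Reciprocal rank at k
#'
#' `1 / rank` of the first predicted term that is in the gold set `T`,
#' considering the top-`k` predictions only; 0 when none of the top-`k`
#' terms is in `T`.
#'
#' @param gold character vector of gold-standard accessions (non-empty).
#' @param pred a `gota_prediction` or character vector of ranked
#'   accessions.
#' @param k rank cutoff (default 10).
#' @return value in `[0, 1]`.
#' @export
rr_at_k <- function(gold, pred, k = 10L) {
  if (length(gold) == 0L) stop("empty gold-standard set")
  top <- utils::head(.pred_terms(pred), k)
  hit <- which(top %in% gold)
  if (length(hit) == 0L) 0 else 1 / hit[1]
}

#' Recall at k
#'
#' Fraction of the gold-standard terms recovered among the top-`k`
#' predictions: `|T  intersect  P_k| / |T|`.
#'
#' @inheritParams rr_at_k
#' @return value in `[0, 1]`.
#' @export
recall_at_k <- function(gold, pred, k = 10L) {
  if (length(gold) == 0L) stop("empty gold-standard set")
  gold <- unique(gold)
  top <- utils::head(.pred_terms(pred), k)
  length(intersect(gold, top)) / length(gold)
}

#' Hierarchical precision, recall and F at k
#'
#' Precision and recall computed on ancestor closures instead of raw term
#' sets: with `A(X)` the closure of `X` up to the root(s) (including `X`),
#' `hP = |A(T) n A(P_k)| / |A(P_k)|` and `hR = |A(T) n A(P_k)| / |A(T)|`;
#' `hF` is their harmonic mean (0 when both are 0). An empty prediction
#' yields `hP = hR = 0`, the CAFA convention.
#'
#' Note that `hP` rewards generic predictions: predicting only a root term
#' whose closure is inside `A(T)` gives `hP = 1`, which is why recall and
#' the threshold-swept F-max carry more weight in practice.
#'
#' @param onto a `gota_ontology`.
#' @inheritParams rr_at_k
#' @return named numeric vector `c(hP, hR, hF)`.
#' @export
hier_pr_at_k <- function(onto, gold, pred, k = 10L) {
  if (length(gold) == 0L) stop("empty gold-standard set")
  top <- utils::head(.pred_terms(pred), k)
  .hier_pr(onto, gold, top)
}

.hier_pr <- function(onto, gold, predicted) {
  at <- ancestors(onto, gold)
  if (length(predicted) == 0L) return(c(hP = 0, hR = 0, hF = 0))
  ap <- ancestors(onto, predicted)
  overlap <- length(intersect(at, ap))
  hp <- overlap / length(ap)
  hr <- overlap / length(at)
  hf <- if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr)
  c(hP = hp, hR = hr, hF = hf)
}

#' CAFA hierarchical F-max over score thresholds
#'
#' Sweeps a score threshold `s` over the distinct prediction scores
#' observed in the dataset. At each threshold the prediction sets `P_s`
#' (terms scoring `>= s`) replace the rank cutoff: average hierarchical
#' precision is taken over the pairs with a non-empty `P_s` only, while
#' average hierarchical recall is taken over *all* pairs (empty
#' predictions contribute recall 0). The result is the maximum harmonic
#' mean of the two averages and the threshold attaining it. Sweeping the
#' observed score set (rather than a fixed grid) finds the exact maximum
#' with finite work, since the averages only change at observed scores.
#'
#' @param onto a `gota_ontology`.
#' @param dataset an evaluation dataset: list of pairs, each a list with
#'   elements `gold` (character vector) and `pred` (a `gota_prediction`).
#' @return named list with `hF_max` and `threshold`.
#' @export
cafa_hf_max <- function(onto, dataset) {
  if (length(dataset) == 0L) stop("empty evaluation dataset")
  scores <- unlist(lapply(dataset, function(d) .pred_scores(d$pred)),
                   use.names = FALSE)
  if (length(scores) == 0L) stop("no prediction carries a score")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  at <- lapply(dataset, function(d) ancestors(onto, d$gold))

  best <- c(hF_max = 0, threshold = thresholds[1])
  for (s in thresholds) {
    hps <- numeric(0)
    hrs <- numeric(length(dataset))
    for (i in seq_along(dataset)) {
      d <- dataset[[i]]
      terms <- .pred_terms(d$pred)[.pred_scores(d$pred) >= s]
      if (length(terms) == 0L) next
      ap <- ancestors(onto, terms)
      overlap <- length(intersect(at[[i]], ap))
      hps <- c(hps, overlap / length(ap))
      hrs[i] <- overlap / length(at[[i]])
    }
    if (length(hps) == 0L) next
    hp <- mean(hps)
    hr <- mean(hrs)
    hf <- if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr)
    if (hf > best[["hF_max"]]) best <- c(hF_max = hf, threshold = s)
  }
  as.list(best)
}

#' Information-theoretic precision and recall at k
#'
#' Both sets are first leaf-reduced (generic ancestors stripped), then each
#' remaining term is credited with its best Lin similarity against the
#' other side: `iP_k` averages over the predicted leaves, `iR_k` over the
#' gold leaves. Predicting only terms whose sole common ancestor with the
#' gold set is a root scores 0 — unlike hierarchical precision, these
#' metrics do not reward generic predictions.
#'
#' @param onto a `gota_ontology`.
#' @param ict a `gota_ic` table.
#' @inheritParams rr_at_k
#' @return value in `[0, 1]`.
#' @export
it_precision_at_k <- function(onto, ict, gold, pred, k = 10L) {
  if (length(gold) == 0L) stop("empty gold-standard set")
  top <- utils::head(.pred_terms(pred), k)
  if (length(top) == 0L) return(0)
  lp <- leaves(onto, top)
  lt <- leaves(onto, gold)
  mean(vapply(lp, function(p) {
    max(vapply(lt, function(t) lin(onto, ict, t, p), numeric(1)))
  }, numeric(1)))
}

#' @rdname it_precision_at_k
#' @export
it_recall_at_k <- function(onto, ict, gold, pred, k = 10L) {
  if (length(gold) == 0L) stop("empty gold-standard set")
  top <- utils::head(.pred_terms(pred), k)
  if (length(top) == 0L) return(0)
  lp <- leaves(onto, top)
  lt <- leaves(onto, gold)
  mean(vapply(lt, function(t) {
    max(vapply(lp, function(p) lin(onto, ict, t, p), numeric(1)))
  }, numeric(1)))
}

#' Evaluate a prediction dataset
#'
#' Computes the per-query metric suite and its means: reciprocal rank and
#' recall at `k`, hierarchical precision/recall/F at `k`,
#' information-theoretic precision at 1 and recall at `k`, plus the
#' dataset-level threshold-swept hierarchical F-max. The defaults mirror
#' the usual top-10 evaluation focus. An optional per-namespace breakdown
#' restricts gold and predictions to one namespace before computing ranks.
#'
#' @param onto a `gota_ontology`.
#' @param ict a `gota_ic` table.
#' @param dataset list of pairs, each a list with `gold` (character
#'   vector) and `pred` (a `gota_prediction`); optionally named by query.
#' @param k rank cutoff (default 10).
#' @param namespace optional namespace code (`"BP"`, `"MF"`, `"CC"`) to
#'   restrict the evaluation to.
#' @return an object of class `gota_evaluation`: list with `per_query`
#'   (data frame, one row per pair), `summary` (named numeric vector of
#'   means plus `hF_max`) and `k`.
#' @export
evaluate <- function(onto, ict, dataset, k = 10L, namespace = NULL) {
  if (length(dataset) == 0L) stop("empty evaluation dataset")
  if (!is.null(namespace)) {
    ns <- vapply(onto$terms, function(t) {
      if (is.na(t$namespace)) "unset" else t$namespace
    }, character(1))
    in_ns <- names(ns)[ns == namespace]
    dataset <- lapply(dataset, function(d) {
      keep <- d$pred$ranked$term %in% in_ns
      d$pred$ranked <- d$pred$ranked[keep, , drop = FALSE]
      d$gold <- intersect(d$gold, in_ns)
      d
    })
    dataset <- Filter(function(d) length(d$gold) > 0L, dataset)
    if (length(dataset) == 0L) stop("no query has gold terms in namespace ",
                                    namespace)
  }
  rows <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    if (length(.pred_scores(d$pred)) !=
        length(.pred_terms(d$pred))) {
      stop("prediction ", i, " has missing scores")
    }
    h <- hier_pr_at_k(onto, d$gold, d$pred, k)
    data.frame(
      query = if (!is.null(names(dataset))) names(dataset)[i] else
        as.character(i),
      rr = rr_at_k(d$gold, d$pred, k),
      recall = recall_at_k(d$gold, d$pred, k),
      hP = h[["hP"]], hR = h[["hR"]], hF = h[["hF"]],
      iP1 = it_precision_at_k(onto, ict, d$gold, d$pred, 1L),
      iR = it_recall_at_k(onto, ict, d$gold, d$pred, k),
      stringsAsFactors = FALSE
    )
  })
  per_query <- do.call(rbind, rows)
  hfm <- cafa_hf_max(onto, dataset)
  summary <- c(
    MRR = mean(per_query$rr), R = mean(per_query$recall),
    hP = mean(per_query$hP), hR = mean(per_query$hR),
    hF = mean(per_query$hF), iP1 = mean(per_query$iP1),
    iR = mean(per_query$iR), hF_max = hfm$hF_max
  )
  structure(list(per_query = per_query, summary = summary, k = k),
            class = "gota_evaluation")
}

#' @export
print.gota_evaluation <- function(x, ...) {
  cat("gota evaluation over", nrow(x$per_query), "queries (k =", x$k, ")\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write an evaluation report
#'
#' One TSV row per query plus a `mean` summary row (with the dataset-level
#' `hF_max` appended as its own column on the summary row).
#'
#' @param ev a `gota_evaluation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(ev, path) {
  stopifnot(inherits(ev, "gota_evaluation"))
  pq <- ev$per_query
  num <- vapply(pq[-1], function(col) formatC(col, format = "g", digits = 10),
                character(nrow(pq)))
  num <- matrix(num, nrow = nrow(pq))
  lines <- c(
    paste(c(colnames(pq), "hF_max"), collapse = "\t"),
    vapply(seq_len(nrow(pq)), function(i) {
      paste(c(pq$query[i], num[i, ], ""), collapse = "\t")
    }, character(1)),
    paste(c("mean",
            formatC(unname(ev$summary[c("MRR", "R", "hP", "hR", "hF",
                                        "iP1", "iR")]),
                    format = "g", digits = 10),
            formatC(ev$summary[["hF_max"]], format = "g", digits = 10)),
          collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
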