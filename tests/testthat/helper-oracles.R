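# Independent brute-force oracles and small fixture builders. Everything
# here is deliberately naive (recursion, double loops, dense arithmetic)
# and shares no code with the package internals it checks.

# ---- fixture builders -------------------------------------------------------

# A fixed 6-term DAG used across unit tests:
#   root -> a -> c -> leaf ; root -> b -> c ; root -> b -> d
chain_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root process", "",
    "[Term]", "id: GO:0000002", "name: alpha signaling",
    "synonym: \"alpha cascade\" EXACT []", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "name: beta transport", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: gamma binding",
    "is_a: GO:0000002", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: delta fusion", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000006", "name: epsilon docking",
    "is_a: GO:0000004", "")
}

chain_onto <- function() parse_obo(chain_obo())

# Random layered DAG as OBO text: term i (i >= 2) draws 1-2 parents among
# the earlier terms. Returns a parsed ontology.
rand_onto <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n))
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term", i, " node", i))
    if (i > 1L) {
      k <- sample(1:min(2L, i - 1L), 1L)
      for (p in sample(ids[seq_len(i - 1L)], k)) {
        lines <- c(lines, paste0("is_a: ", p))
      }
    }
    lines <- c(lines, "")
  }
  parse_obo(lines)
}

# Random annotation set over an ontology (excluding the first/root term).
rand_gold <- function(onto, n_docs, seed, max_terms = 4L) {
  set.seed(seed)
  ids <- setdiff(names(onto$terms), onto$roots)
  sets <- lapply(seq_len(n_docs), function(i) {
    sample(ids, sample.int(min(max_terms, length(ids)), 1L))
  })
  names(sets) <- sprintf("d%03d", seq_len(n_docs))
  annotation_set(sets)
}

# A tiny hand-built knowledge base over chain_onto().
tiny_kb <- function() {
  pubs <- list(
    publication("p1", title = "alpha signaling in yeast cells",
                abstract = "the alpha cascade drives signaling output",
                references = c("p2", "x9"), year = 2000L),
    publication("p2", title = "beta transport channels",
                abstract = "membrane beta transport is selective",
                references = "p1", year = 2004L),
    publication("p3", title = "gamma binding assay",
                abstract = "we measure gamma binding affinity",
                references = c("p1", "p2"), year = 2010L),
    publication("p4", title = "delta fusion imaging", abstract = "",
                year = 1998L)
  )
  gold <- annotation_set(list(
    p1 = "GO:0000002", p2 = "GO:0000003",
    p3 = c("GO:0000004", "GO:0000002"), p4 = "GO:0000005"
  ))
  build_kb(pubs, gold, chain_onto(), quiet = TRUE)
}

# ---- DAG oracles ------------------------------------------------------------

# Recursive DFS ancestor closure (includes X).
brute_ancestors <- function(onto, x) {
  seen <- character(0)
  visit <- function(t) {
    if (t %in% seen) return(invisible())
    seen <<- c(seen, t)
    for (p in onto$parents[[t]]) visit(p)
  }
  for (t in x) visit(t)
  sort(seen)
}

# Pairwise filter: drop u if u is an ancestor of some other v.
brute_leaves <- function(onto, x) {
  keep <- vapply(x, function(u) {
    !any(vapply(setdiff(x, u), function(v) {
      u %in% brute_ancestors(onto, v)
    }, logical(1)))
  }, logical(1))
  sort(x[keep])
}

# Count-and-log information content (propagated), independent of the
# package's counting code.
brute_ic <- function(onto, gold) {
  ids <- names(onto$terms)
  counts <- setNames(integer(length(ids)), ids)
  for (terms in gold) {
    hit <- brute_ancestors(onto, terms)
    counts[hit] <- counts[hit] + 1L
  }
  ic <- -log(counts / length(gold))
  cap <- max(ic[is.finite(ic)])
  ic[!is.finite(ic)] <- cap
  ic
}

brute_resnik <- function(onto, ict, t, p) {
  common <- intersect(brute_ancestors(onto, t), brute_ancestors(onto, p))
  if (length(common) == 0L) 0 else max(ict[common])
}

brute_lin <- function(onto, ict, t, p) {
  d <- ict[[t]] + ict[[p]]
  if (d == 0) 0 else 2 * brute_resnik(onto, ict, t, p) / d
}

# ---- metric oracles ---------------------------------------------------------

brute_hier <- function(onto, gold, predicted) {
  at <- brute_ancestors(onto, gold)
  if (length(predicted) == 0L) return(c(hP = 0, hR = 0, hF = 0))
  ap <- brute_ancestors(onto, predicted)
  ov <- length(intersect(at, ap))
  hp <- ov / length(ap); hr <- ov / length(at)
  c(hP = hp, hR = hr, hF = if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr))
}

brute_hfmax <- function(onto, dataset) {
  scores <- unlist(lapply(dataset, function(d) d$pred$ranked$score))
  best <- 0
  for (s in sort(unique(scores))) {
    hps <- c(); hrs <- c()
    for (d in dataset) {
      keep <- d$pred$ranked$score >= s
      terms <- d$pred$ranked$term[keep]
      h <- brute_hier(onto, d$gold, terms)
      if (length(terms) > 0L) hps <- c(hps, h[["hP"]])
      hrs <- c(hrs, h[["hR"]])
    }
    if (length(hps) == 0L) next
    hp <- mean(hps); hr <- mean(hrs)
    hf <- if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr)
    best <- max(best, hf)
  }
  best
}

brute_ip <- function(onto, ict, gold, predicted) {
  lp <- brute_leaves(onto, predicted); lt <- brute_leaves(onto, gold)
  mean(sapply(lp, function(p) max(sapply(lt, function(t) {
    brute_lin(onto, ict, t, p)
  }))))
}

brute_ir <- function(onto, ict, gold, predicted) {
  lp <- brute_leaves(onto, predicted); lt <- brute_leaves(onto, gold)
  mean(sapply(lt, function(t) max(sapply(lp, function(p) {
    brute_lin(onto, ict, t, p)
  }))))
}

# ---- dense text oracles -----------------------------------------------------

brute_cosine <- function(x, y) {
  feats <- union(names(x), names(y))
  xd <- setNames(numeric(length(feats)), feats); xd[names(x)] <- x
  yd <- setNames(numeric(length(feats)), feats); yd[names(y)] <- y
  if (sum(xd^2) == 0 || sum(yd^2) == 0) return(0)
  sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
}

# Full-scan scoring oracle: recompute the combined score of every candidate
# term for a query from the raw feature definitions (products of
# (1 + feature)^exponent, annotation transfer from the top-K).
brute_predict <- function(q, raw_text, idx, params) {
  pmids <- setdiff(names(idx$pubs), q$pmid)
  phi <- sapply(pmids, function(pm) {
    p <- idx$pubs[[pm]]
    f1 <- brute_cosine(q$W, p$W); f2 <- brute_cosine(q$T, p$T)
    f3 <- brute_cosine(q$R, p$R)
    f4 <- if (is.na(q$Y) || is.na(p$Y) || abs(q$Y - p$Y) > 50) 0 else
      (50 - abs(q$Y - p$Y)) / 50
    (1 + f1)^params$m[1] * (1 + f2)^params$m[2] *
      (1 + f3)^params$m[3] * (1 + f4)^params$m[4]
  })
  ord <- order(-phi, pmids)
  top <- ord[seq_len(min(params$K, length(ord)))]
  phi_p <- list()
  for (i in top) {
    for (t in idx$gold[[pmids[i]]]) {
      phi_p[[t]] <- (if (is.null(phi_p[[t]])) 0 else phi_p[[t]]) +
        unname(phi[i])
    }
  }
  scores <- sapply(names(phi_p), function(tid) {
    t <- idx$terms[[tid]]
    g1 <- brute_cosine(q$W, t$W); g2 <- brute_cosine(q$T, t$T)
    g3 <- length(intersect(t$title_stems, names(q$W))) / length(t$title_stems)
    text <- trimws(gsub("\\s+", " ", tolower(raw_text)))
    cnt <- 0L
    for (ph in t$phrases) {
      hits <- gregexpr(ph, text, fixed = TRUE)[[1]]
      if (hits[1] != -1L) cnt <- cnt + length(hits)
    }
    g4 <- min(cnt, 4L) / 4
    g5 <- if (is.na(q$Y) || is.na(t$Y) || abs(q$Y - t$Y) > 50) 0 else
      (50 - abs(q$Y - t$Y)) / 50
    phit <- (1 + g1)^params$n[1] * (1 + g2)^params$n[2] *
      (1 + g3)^params$n[3] * (1 + g4)^params$n[4] * (1 + g5)^params$n[5]
    phi_p[[tid]] * phit
  })
  terms <- names(scores)
  ord <- order(-scores, terms)
  data.frame(term = terms[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}
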