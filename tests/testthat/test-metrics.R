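# Rank metrics, hierarchical precision/recall, threshold-swept F-max and
# the information-theoretic counterparts.

fake_pred <- function(terms, scores = rev(seq_along(terms))) {
  structure(
    list(query_id = "q",
         ranked = data.frame(term = terms, score = as.numeric(scores),
                             stringsAsFactors = FALSE)),
    class = "gota_prediction"
  )
}

test_that("reciprocal rank and recall at k behave at the boundaries", {
  gold <- c("GO:0000004", "GO:0000005")
  expect_equal(rr_at_k(gold, fake_pred(c("GO:0000004", "x"))), 1)
  expect_equal(rr_at_k(gold, fake_pred(c("a", "b", "GO:0000005"))), 1 / 3)
  expect_equal(rr_at_k(gold, fake_pred(c("a", "b"))), 0)
  expect_equal(rr_at_k(gold, fake_pred(c(rep("x", 10), "GO:0000004")),
                       k = 10), 0)
  expect_equal(recall_at_k(c("t1", "t2", "t3", "t4"),
                           fake_pred(c("t1", "t3", "z"))), 0.5)
  expect_equal(recall_at_k(gold, fake_pred(c(gold, "extra"))), 1)
  expect_equal(recall_at_k(gold, fake_pred(c("a", "b"))), 0)
  expect_error(rr_at_k(character(0), fake_pred("a")), "empty")
  # both are non-decreasing in k
  p <- fake_pred(c("a", "GO:0000004", "b", "GO:0000005"))
  rr <- sapply(1:4, function(k) rr_at_k(gold, p, k))
  rc <- sapply(1:4, function(k) recall_at_k(gold, p, k))
  expect_true(all(diff(rr) >= 0))
  expect_true(all(diff(rc) >= 0))
})

test_that("hierarchical precision/recall match the set-algebra oracle", {
  onto <- chain_onto()
  gold <- c("GO:0000006", "GO:0000005")
  # perfect prediction
  expect_equal(hier_pr_at_k(onto, gold, fake_pred(gold)),
               c(hP = 1, hR = 1, hF = 1))
  # predicting only the root: closure is inside A(T), so hP = 1 while the
  # recall collapses — the known generic-prediction failure mode
  h_root <- hier_pr_at_k(onto, gold, fake_pred("GO:0000001"))
  expect_equal(h_root[["hP"]], 1)
  expect_lt(h_root[["hR"]], 0.2)
  # random pairs on random DAGs against the brute-force oracle
  for (seed in 1:8) {
    o <- rand_onto(15L, 40L + seed)
    ids <- names(o$terms)
    set.seed(seed)
    T_set <- sample(ids, sample(1:4, 1))
    P_set <- sample(ids, sample(1:6, 1))
    expect_equal(hier_pr_at_k(o, T_set, fake_pred(P_set), k = 10),
                 brute_hier(o, T_set, P_set), tolerance = 1e-12)
  }
})

test_that("hF_max equals the exhaustive threshold sweep", {
  onto <- chain_onto()
  # perfect single pair at the top score
  d1 <- list(list(gold = "GO:0000006", pred = fake_pred("GO:0000006", 5)))
  r1 <- cafa_hf_max(onto, d1)
  expect_equal(r1$hF_max, 1)
  expect_equal(r1$threshold, 5)
  # every prediction equals its gold set at top score
  d2 <- list(
    list(gold = c("GO:0000004", "GO:0000002"),
         pred = fake_pred(c("GO:0000004", "GO:0000002", "GO:0000005"),
                          c(9, 9, 1))),
    list(gold = "GO:0000005", pred = fake_pred(c("GO:0000005", "GO:0000003"),
                                               c(8, 2)))
  )
  expect_equal(cafa_hf_max(onto, d2)$hF_max, brute_hfmax(onto, d2),
               tolerance = 1e-12)
  # 5-pair random fixture
  o <- rand_onto(14L, 77L)
  ids <- names(o$terms)
  set.seed(78)
  d3 <- lapply(1:5, function(i) {
    n <- sample(2:5, 1)
    list(gold = sample(ids, sample(1:3, 1)),
         pred = fake_pred(sample(ids, n), round(runif(n, 0, 5), 1)))
  })
  expect_equal(cafa_hf_max(o, d3)$hF_max, brute_hfmax(o, d3),
               tolerance = 1e-12)
  # the max dominates the harmonic mean at every single threshold
  hfm <- cafa_hf_max(o, d3)$hF_max
  for (s in c(0.5, 1, 2.5, 4)) {
    hps <- c(); hrs <- c()
    for (d in d3) {
      terms <- d$pred$ranked$term[d$pred$ranked$score >= s]
      h <- brute_hier(o, d$gold, terms)
      if (length(terms)) hps <- c(hps, h[["hP"]])
      hrs <- c(hrs, h[["hR"]])
    }
    if (!length(hps)) next
    hp <- mean(hps); hr <- mean(hrs)
    expect_lte(if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr), hfm + 1e-12)
  }
})

test_that("information-theoretic metrics match the double-loop oracle", {
  onto <- chain_onto()
  gold_all <- annotation_set(list(
    d1 = "GO:0000006", d2 = "GO:0000004", d3 = "GO:0000002",
    d4 = "GO:0000005", d5 = "GO:0000005"
  ))
  ict <- information_content(onto, gold_all)
  gold <- c("GO:0000006", "GO:0000005")
  expect_equal(it_precision_at_k(onto, ict, gold, fake_pred(gold)), 1)
  expect_equal(it_recall_at_k(onto, ict, gold, fake_pred(gold)), 1)
  # predictions sharing only the root with the gold set score 0
  expect_equal(it_precision_at_k(onto, ict, "GO:0000005",
                                 fake_pred("GO:0000002")), 0)
  # leaf reduction: adding ancestors of predicted terms changes nothing
  with_anc <- fake_pred(c("GO:0000006", "GO:0000004", "GO:0000005",
                          "GO:0000001"))
  expect_equal(it_precision_at_k(onto, ict, gold, with_anc),
               it_precision_at_k(onto, ict, gold,
                                 fake_pred(c("GO:0000006", "GO:0000005"))))
  for (seed in 1:8) {
    o <- rand_onto(15L, 60L + seed)
    g <- rand_gold(o, 10L, 61L + seed)
    ic2 <- information_content(o, g)
    ids <- setdiff(names(o$terms), o$roots)
    set.seed(seed)
    T_set <- sample(ids, sample(1:4, 1))
    P_set <- sample(ids, sample(1:6, 1))
    expect_equal(it_precision_at_k(o, ic2, T_set, fake_pred(P_set), 10),
                 brute_ip(o, ic2, T_set, P_set), tolerance = 1e-12)
    expect_equal(it_recall_at_k(o, ic2, T_set, fake_pred(P_set), 10),
                 brute_ir(o, ic2, T_set, P_set), tolerance = 1e-12)
  }
})

test_that("evaluate aggregates per-query metrics into hand-checked means", {
  onto <- chain_onto()
  gold_all <- annotation_set(list(
    d1 = "GO:0000006", d2 = "GO:0000004", d3 = "GO:0000002",
    d4 = "GO:0000005"
  ))
  ict <- information_content(onto, gold_all)
  ds <- list(
    q1 = list(gold = "GO:0000006",
              pred = fake_pred(c("GO:0000006", "GO:0000003"), c(3, 1))),
    q2 = list(gold = c("GO:0000004", "GO:0000005"),
              pred = fake_pred(c("GO:0000002", "GO:0000004"), c(4, 2)))
  )
  ev <- evaluate(onto, ict, ds)
  expect_equal(unname(ev$summary["MRR"]), mean(c(1, 1 / 2)))
  expect_equal(unname(ev$summary["R"]), mean(c(1, 1 / 2)))
  expect_equal(nrow(ev$per_query), 2L)
  expect_equal(unname(ev$summary["iR"]),
               mean(c(brute_ir(onto, ict, "GO:0000006",
                               c("GO:0000006", "GO:0000003")),
                      brute_ir(onto, ict, c("GO:0000004", "GO:0000005"),
                               c("GO:0000002", "GO:0000004")))),
               tolerance = 1e-12)
  # one perfect prediction: every rank metric is 1
  perfect <- list(list(gold = "GO:0000006", pred = fake_pred("GO:0000006")))
  evp <- evaluate(onto, ict, perfect)
  expect_equal(unname(evp$summary[c("MRR", "R", "hR", "iR", "hF_max")]),
               rep(1, 5))
  # report round-trip: the summary row carries the same means
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(ev, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$rr[tab$query == "mean"], unname(ev$summary["MRR"]),
               tolerance = 1e-9)
})
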