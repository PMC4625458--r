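# OBO parsing, DAG traversal, information content, Resnik/Lin similarity.

test_that("parse_obo reads stanzas, drops obsolete terms, finds roots", {
  onto <- parse_obo(c(
    "[Term]", "id: GO:1", "name: root",
    "[Term]", "id: GO:2", "name: a", "is_a: GO:1",
    "[Term]", "id: GO:3", "name: b", "is_a: GO:1 ! root",
    "[Term]", "id: GO:4", "name: gone", "is_obsolete: true"
  ))
  expect_length(onto$terms, 3L)
  expect_identical(onto$roots, "GO:1")
  expect_false("GO:4" %in% names(onto$terms))
})

test_that("parse_obo honours synonyms, def, namespace and part_of", {
  onto <- chain_onto()
  expect_identical(onto$terms[["GO:0000002"]]$synonyms, "alpha cascade")
  with_po <- parse_obo(c(
    "[Term]", "id: GO:1", "name: root", "namespace: molecular_function",
    "[Term]", "id: GO:2", "name: part", "def: \"a part\" [ref]",
    "relationship: part_of GO:1"
  ))
  expect_identical(with_po$terms[["GO:2"]]$parents, "GO:1")
  expect_identical(with_po$terms[["GO:1"]]$namespace, "MF")
  expect_identical(with_po$terms[["GO:2"]]$description, "a part")
  no_po <- parse_obo(c(
    "[Term]", "id: GO:1", "name: root",
    "[Term]", "id: GO:2", "name: part", "relationship: part_of GO:1"
  ), include_part_of = FALSE)
  expect_length(no_po$roots, 2L)
})

test_that("parse_obo rejects undeclared parents and cycles", {
  expect_error(parse_obo(c("[Term]", "id: GO:1", "name: x", "is_a: GO:9")),
               "GO:9")
  expect_error(parse_obo(c(
    "[Term]", "id: GO:1", "name: a", "is_a: GO:2",
    "[Term]", "id: GO:2", "name: b", "is_a: GO:1"
  )), "cycle")
})

test_that("ancestor closure contains X, is closed and idempotent", {
  onto <- chain_onto()
  expect_identical(ancestors(onto, "GO:0000001"), "GO:0000001")
  expect_setequal(ancestors(onto, "GO:0000006"),
                  c("GO:0000006", "GO:0000004", "GO:0000002", "GO:0000003",
                    "GO:0000001"))
  for (seed in 1:5) {
    o <- rand_onto(10L, seed)
    x <- sample(names(o$terms), 3L)
    a <- ancestors(o, x)
    expect_setequal(a, brute_ancestors(o, x))
    expect_setequal(ancestors(o, a), a)
    expect_true(all(x %in% a))
  }
  expect_error(ancestors(onto, "GO:9999999"), "GO:9999999")
})

test_that("leaf reduction is the maximal antichain", {
  onto <- chain_onto()
  expect_setequal(leaves(onto, c("GO:0000001", "GO:0000002", "GO:0000004")),
                  "GO:0000004")
  antichain <- c("GO:0000005", "GO:0000006")
  expect_setequal(leaves(onto, antichain), antichain)
  expect_error(leaves(onto, character(0)), "empty")
  for (seed in 1:5) {
    o <- rand_onto(15L, seed + 10L)
    x <- sample(names(o$terms), 6L)
    l <- leaves(o, x)
    expect_setequal(l, brute_leaves(o, x))
    expect_true(all(l %in% x))
    # every removed element is an ancestor of a kept one
    expect_true(all(x %in% brute_ancestors(o, l)))
  }
})

test_that("information content matches direct count-and-log oracle", {
  onto <- chain_onto()
  gold <- annotation_set(list(
    d1 = "GO:0000006", d2 = "GO:0000004", d3 = "GO:0000002",
    d4 = c("GO:0000005", "GO:0000002")
  ))
  ict <- information_content(onto, gold)
  expect_equal(unname(ict["GO:0000001"]), 0)         # root in all, propagated
  expect_equal(unname(ict["GO:0000006"]), log(4))    # 1 of 4 documents
  oracle <- brute_ic(onto, gold)
  expect_equal(as.numeric(ict[names(oracle)]), unname(oracle),
               tolerance = 1e-12)
  # antitone along parent edges
  for (id in names(onto$terms)) {
    for (pa in onto$parents[[id]]) {
      expect_lte(ict[[pa]], ict[[id]] + 1e-12)
    }
  }
  # synthetic 10-doc corpus on a random DAG
  o <- rand_onto(12L, 3L)
  g <- rand_gold(o, 10L, 4L)
  expect_equal(as.numeric(information_content(o, g)[names(o$terms)]),
               unname(brute_ic(o, g)[names(o$terms)]), tolerance = 1e-12)
})

test_that("unpropagated information content counts direct annotations", {
  onto <- chain_onto()
  gold <- annotation_set(list(d1 = "GO:0000006", d2 = "GO:0000004"))
  raw <- information_content(onto, gold, propagate = FALSE)
  expect_equal(unname(raw["GO:0000006"]), log(2))
  # root never directly annotated -> capped at the max observed ic
  expect_equal(unname(raw["GO:0000001"]), attr(raw, "ic_max"))
})

test_that("Resnik and Lin match hand-enumerated common ancestors", {
  onto <- chain_onto()
  gold <- annotation_set(list(
    d1 = "GO:0000006", d2 = "GO:0000004", d3 = "GO:0000002",
    d4 = "GO:0000005"
  ))
  ict <- information_content(onto, gold)
  expect_equal(resnik(onto, ict, "GO:0000006", "GO:0000006"),
               unname(ict["GO:0000006"]))
  # siblings under GO:0000003 (ic = -ln(2/4)): common ancestors are the
  # root (0) and GO:0000003
  expect_equal(resnik(onto, ict, "GO:0000004", "GO:0000005"),
               unname(ict["GO:0000003"]))
  # only common ancestor is the root
  expect_equal(resnik(onto, ict, "GO:0000002", "GO:0000005"), 0)
  expect_equal(lin(onto, ict, "GO:0000002", "GO:0000005"), 0)
  expect_equal(lin(onto, ict, "GO:0000006", "GO:0000006"), 1)
  # exhaustive symmetry/bounds on a fixture DAG
  o <- rand_onto(18L, 5L)
  g <- rand_gold(o, 12L, 6L)
  ic2 <- information_content(o, g)
  ids <- names(o$terms)
  for (t in ids) {
    for (p in ids) {
      v <- lin(o, ic2, t, p)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, lin(o, ic2, p, t))
      expect_equal(resnik(o, ic2, t, p), brute_resnik(o, ic2, t, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("terms in different namespaces have zero Resnik similarity", {
  onto <- parse_obo(c(
    "[Term]", "id: GO:1", "name: bp root", "namespace: biological_process",
    "[Term]", "id: GO:2", "name: mf root", "namespace: molecular_function",
    "[Term]", "id: GO:3", "name: bp leaf", "is_a: GO:1",
    "[Term]", "id: GO:4", "name: mf leaf", "is_a: GO:2"
  ))
  gold <- annotation_set(list(d1 = "GO:3", d2 = "GO:4"))
  ict <- information_content(onto, gold)
  expect_equal(resnik(onto, ict, "GO:3", "GO:4"), 0)
})
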