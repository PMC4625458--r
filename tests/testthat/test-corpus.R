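# Publication records, annotation readers, knowledge-base assembly.

pubmed_xml <- function() {
  paste0(
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>11</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>2001</Year></PubDate>",
    "</JournalIssue></Journal>",
    "<ArticleTitle>Alpha signaling</ArticleTitle>",
    "<Abstract><AbstractText Label=\"BG\">Part one.</AbstractText>",
    "<AbstractText>Part two.</AbstractText>",
    "<AbstractText>Part three.</AbstractText></Abstract>",
    "</Article>",
    "<CommentsCorrectionsList>",
    "<CommentsCorrections RefType=\"Cites\"><PMID>99</PMID>",
    "</CommentsCorrections>",
    "<CommentsCorrections RefType=\"ErratumIn\"><PMID>98</PMID>",
    "</CommentsCorrections>",
    "</CommentsCorrectionsList>",
    "</MedlineCitation>",
    "<PubmedData><ReferenceList><Reference><ArticleIdList>",
    "<ArticleId IdType=\"pubmed\">77</ArticleId>",
    "</ArticleIdList></Reference></ReferenceList></PubmedData>",
    "</PubmedArticle>",
    "<PubmedArticle><MedlineCitation><PMID>12</PMID><Article>",
    "<ArticleTitle>Title only</ArticleTitle></Article></MedlineCitation>",
    "</PubmedArticle>",
    "</PubmedArticleSet>"
  )
}

test_that("read_pubmed_xml extracts fields and tolerates sparse records", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(pubmed_xml(), path)
  pubs <- read_pubmed_xml(path)
  expect_length(pubs, 2L)
  p <- pubs[[1]]
  expect_identical(p$pmid, "11")
  expect_identical(p$abstract, "Part one. Part two. Part three.")
  expect_identical(p$year, 2001L)
  # ReferenceList and Cites-type comments both contribute; ErratumIn does not
  expect_setequal(p$references, c("77", "99"))
  # title-only record keeps empty abstract, no refs, no year
  q <- pubs[[2]]
  expect_identical(q$abstract, "")
  expect_length(q$references, 0L)
  expect_true(is.na(q$year))
  empty <- read_pubmed_xml(xml2::read_xml("<PubmedArticleSet/>"))
  expect_length(empty, 0L)
})

test_that("GAF reader keeps only PMID references and collapses duplicates", {
  gaf <- c(
    "!gaf-version: 2.1",
    paste("UniProt", "P1", "geneA", "", "GO:0005634", "PMID:123", "IDA",
          sep = "\t"),
    paste("UniProt", "P2", "geneB", "", "GO:0005634", "PMID:123|PMID:456",
          "IDA", sep = "\t"),
    paste("UniProt", "P3", "geneC", "", "GO:0008150",
          "Reactome:R-HSA-123", "TAS", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".gaf")
  writeLines(gaf, path)
  ann <- read_annotations(path, format = "gaf")
  expect_setequal(names(ann), c("123", "456"))
  expect_identical(ann[["123"]], "GO:0005634")  # duplicate pair stored once
  # a GAF and a TSV with the same content parse identically
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("123\tGO:0005634", "456\tGO:0005634"), tsv)
  expect_identical(read_annotations(tsv, "tsv"), ann)
})

test_that("annotation reader fails on zero pairs and bad accessions", {
  path <- withr::local_tempfile()
  writeLines(paste("DB", "P1", "g", "", "not an id!", "PMID:1", sep = "\t"),
             path)
  expect_warning(expect_error(read_annotations(path, "gaf"), "no.*pairs"),
                 "malformed")
})

test_that("build_kb validates both directions and is idempotent", {
  onto <- chain_onto()
  pubs <- list(
    publication("p1", title = "one"),
    publication("p2", title = "two")
  )
  gold <- annotation_set(list(
    p1 = c("GO:0000002", "GO:9999999"),  # one unknown term
    p2 = "GO:0000003",
    p9 = "GO:0000002"                    # no publication record
  ))
  expect_message(kb <- build_kb(pubs, gold, onto), "dropped")
  expect_setequal(names(kb$publications), c("p1", "p2"))
  expect_identical(kb$gold[["p1"]], "GO:0000002")
  kb2 <- build_kb(kb$publications, kb$gold, onto, quiet = TRUE)
  expect_identical(kb2, kb)
  expect_error(build_kb(pubs, annotation_set(list(zz = "GO:0000002")), onto,
                        quiet = TRUE), "empty")
})

test_that("filter_kb restricts and revalidates", {
  kb <- tiny_kb()
  sub <- filter_kb(kb, c("p1", "p3"))
  expect_setequal(names(sub$publications), c("p1", "p3"))
  expect_setequal(names(sub$gold), c("p1", "p3"))
  expect_identical(filter_kb(kb, names(kb$publications))$gold, kb$gold)
  one <- filter_kb(kb, "p2")
  expect_length(one$publications, 1L)
  expect_error(filter_kb(kb, c("zz", "yy")), "no knowledge-base publication")
})

test_that("publication invariants are enforced", {
  expect_error(publication("", title = "x"), "pmid")
  expect_error(publication("p", title = "", abstract = ""), "neither")
})
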