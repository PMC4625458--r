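# Corpus handling: publication records, annotation readers (GAF / TSV),
# PubMed XML and JSONL corpus readers, knowledge-base assembly.

#' Construct a publication record
#'
#' A publication carries the four raw features the classifier indexes:
#' title, abstract, cited references (PMIDs) and publication year. At least
#' one of title and abstract must be non-empty — the text bag-of-words of a
#' publication is assumed to be always non-null.
#'
#' @param pmid publication identifier (opaque string).
#' @param title title text ("" if unavailable).
#' @param abstract abstract text ("" if unavailable).
#' @param references character vector of cited PMIDs.
#' @param year integer publication year, or `NA` if unknown.
#' @return an object of class `gota_publication`.
#' @export
publication <- function(pmid, title = "", abstract = "",
                        references = character(0), year = NA_integer_) {
  pmid <- as.character(pmid)
  if (!nzchar(pmid)) stop("pmid must be non-empty")
  if (!nzchar(title) && !nzchar(abstract)) {
    stop("publication ", pmid, " has neither title nor abstract")
  }
  structure(
    list(pmid = pmid, title = title, abstract = abstract,
         references = as.character(references),
         year = if (is.na(year)) NA_integer_ else as.integer(year)),
    class = "gota_publication"
  )
}

#' Read publications from PubMed efetch XML
#'
#' Parses a `PubmedArticleSet` document as returned by NCBI efetch.
#' For each article the PMID, `ArticleTitle`, the concatenation of all
#' `AbstractText` segments, the `PubDate/Year` and the cited PMIDs are
#' extracted. References are collected from both `ReferenceList` entries
#' (`ArticleId IdType="pubmed"`) and `CommentsCorrections` elements with
#' `RefType="Cites"` — reference availability in PubMed exports is patchy,
#' so both sources are used. Records lacking abstract, references or year
#' are kept with those fields empty/absent; records without a PMID are
#' skipped with a warning.
#'
#' @param path path to a PubMed XML file (plain or gzip), or an `xml2`
#'   document.
#' @return list of [publication()] records.
#' @export
read_pubmed_xml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  pubs <- list()
  for (art in articles) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("PubmedArticle without PMID skipped")
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    if (is.na(title)) title <- ""
    abst <- paste(
      xml2::xml_text(xml2::xml_find_all(art, ".//Abstract/AbstractText")),
      collapse = " "
    )
    year <- xml2::xml_text(xml2::xml_find_first(
      art, ".//Article/Journal/JournalIssue/PubDate/Year"
    ))
    year <- if (is.na(year)) NA_integer_ else suppressWarnings(as.integer(year))
    refs <- c(
      xml2::xml_text(xml2::xml_find_all(
        art, ".//ReferenceList//ArticleId[@IdType='pubmed']"
      )),
      xml2::xml_text(xml2::xml_find_all(
        art, ".//CommentsCorrections[@RefType='Cites']/PMID"
      ))
    )
    pubs[[length(pubs) + 1L]] <- publication(
      pmid, title = title, abstract = abst,
      references = unique(refs[nzchar(refs)]), year = year
    )
  }
  pubs
}

#' Read publication records from JSONL
#'
#' One JSON object per line with keys `pmid`, `title`, `abstract`, `year`,
#' `references` (the latter four optional). This is the plain-text corpus
#' dialect the synthetic-data writer emits.
#'
#' @param path path to a JSONL file (plain or gzip).
#' @return list of [publication()] records.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    publication(
      pmid = rec$pmid,
      title = if (is.null(rec$title)) "" else rec$title,
      abstract = if (is.null(rec$abstract)) "" else rec$abstract,
      references = if (is.null(rec$references)) character(0) else unlist(rec$references),
      year = if (is.null(rec$year)) NA_integer_ else as.integer(rec$year)
    )
  })
}

#' Construct an annotation set
#'
#' @param assignments named list mapping pmid to a character vector of term
#'   accessions; every entry must be non-empty.
#' @return an object of class `gota_annotations`.
#' @export
annotation_set <- function(assignments) {
  if (length(assignments) == 0L) stop("no annotations")
  if (is.null(names(assignments)) || any(!nzchar(names(assignments)))) {
    stop("assignments must be named by pmid")
  }
  assignments <- lapply(assignments, function(x) sort(unique(as.character(x))))
  if (any(vapply(assignments, length, integer(1)) == 0L)) {
    stop("every annotated pmid must have at least one term")
  }
  structure(assignments[order(names(assignments))], class = "gota_annotations")
}

#' Read gold-standard annotations
#'
#' Reads publication-to-term assignments either from a GAF 2.x gene
#' association file or from a two-column TSV. For GAF input only the GO
#' term (column 5) and the literature reference (column 6) are used; the
#' gene-product columns are discarded and only references of the form
#' `PMID:<id>` produce a pair — a row whose only reference is e.g. a
#' Reactome identifier contributes nothing. Duplicate (pmid, term) pairs
#' (typically the same paper annotating several gene products) are
#' collapsed.
#'
#' @param path path to the file (plain or gzip).
#' @param format `"gaf"` or `"tsv"` (two columns: `pmid<TAB>term`).
#' @return a `gota_annotations` object.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(gzfile(path), warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  pairs <- if (format == "gaf") .parse_gaf_pairs(lines) else .parse_tsv_pairs(lines)
  if (nrow(pairs) == 0L) stop("no (pmid, term) pairs parsed from ", path)
  annotation_set(split(pairs$term, pairs$pmid))
}

.parse_tsv_pairs <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 2L
  if (any(bad)) stop("malformed TSV annotation line: ", lines[which(bad)[1]])
  data.frame(
    pmid = vapply(fields, `[[`, character(1), 1L),
    term = vapply(fields, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

.parse_gaf_pairs <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pmids <- character(0); terms <- character(0)
  for (f in fields) {
    if (length(f) < 6L) next
    term <- f[[5L]]
    if (!grepl("^[A-Za-z]+:[A-Za-z0-9_]+$", term)) {
      warning("malformed term accession skipped: ", term)
      next
    }
    refs <- strsplit(f[[6L]], "|", fixed = TRUE)[[1]]
    hits <- refs[startsWith(refs, "PMID:")]
    if (length(hits) == 0L) next
    ids <- sub("^PMID:", "", hits)
    pmids <- c(pmids, ids)
    terms <- c(terms, rep(term, length(ids)))
  }
  unique(data.frame(pmid = pmids, term = terms, stringsAsFactors = FALSE))
}

#' Build a knowledge base
#'
#' Joins publication records with gold annotations and validates both
#' against the ontology: annotation pairs whose pmid has no publication
#' record or whose term is unknown (or obsolete, since obsolete terms are
#' dropped at OBO parse time) are removed, and publications left without
#' any annotation are dropped. The result is the set of pre-annotated
#' publications queries are compared against.
#'
#' @param pubs list of [publication()] records.
#' @param gold a `gota_annotations` object.
#' @param onto a `gota_ontology`.
#' @param quiet suppress the dropped-record messages.
#' @return an object of class `gota_kb`: list with `publications` (named
#'   list of publication records) and `gold` (a `gota_annotations`
#'   restricted to those pmids).
#' @export
build_kb <- function(pubs, gold, onto, quiet = FALSE) {
  stopifnot(inherits(gold, "gota_annotations"))
  names(pubs) <- vapply(pubs, function(p) p$pmid, character(1))

  known <- names(onto$terms)
  gold2 <- list()
  n_bad_term <- 0L; n_no_pub <- 0L
  for (pmid in names(gold)) {
    if (is.null(pubs[[pmid]])) { n_no_pub <- n_no_pub + 1L; next }
    keep <- intersect(gold[[pmid]], known)
    n_bad_term <- n_bad_term + length(gold[[pmid]]) - length(keep)
    if (length(keep)) gold2[[pmid]] <- keep
  }
  if (length(gold2) == 0L) stop("knowledge base is empty after validation")
  if (!quiet && (n_bad_term > 0L || n_no_pub > 0L)) {
    message("build_kb: dropped ", n_bad_term, " pair(s) with unknown terms, ",
            n_no_pub, " annotated pmid(s) without publication record")
  }
  kept <- names(gold2)
  structure(
    list(publications = pubs[kept], gold = annotation_set(gold2)),
    class = "gota_kb"
  )
}

#' Restrict a knowledge base to a subset of publications
#'
#' Used e.g. to build species-specific knowledge bases from the pmids
#' listed in one species' association file.
#'
#' @param kb a `gota_kb`.
#' @param pmids character vector of pmids to keep.
#' @return a `gota_kb` restricted to `pmids`.
#' @export
filter_kb <- function(kb, pmids) {
  stopifnot(inherits(kb, "gota_kb"))
  keep <- intersect(names(kb$publications), as.character(pmids))
  if (length(keep) == 0L) stop("no knowledge-base publication matches the subset")
  structure(
    list(publications = kb$publications[keep],
         gold = annotation_set(unclass(kb$gold)[keep])),
    class = "gota_kb"
  )
}

#' @export
print.gota_kb <- function(x, ...) {
  n_pairs <- sum(vapply(x$gold, length, integer(1)))
  cat("gota knowledge base:", length(x$publications), "publications,",
      n_pairs, "gold (pmid, term) pairs\n")
  invisible(x)
}
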