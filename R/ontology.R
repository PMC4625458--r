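# Ontology handling: OBO parsing, DAG traversal (ancestor closure, leaf
# reduction), information content and Resnik/Lin term semantic similarity.

#' Parse an OBO-format ontology
#'
#' Reads an OBO 1.2/1.4 flat file into an ontology object. Only `[Term]`
#' stanzas are considered; the fields honoured are `id`, `name`, `synonym`,
#' `namespace`, `def`, `is_a`, `relationship: part_of` and `is_obsolete`.
#' Obsolete terms are dropped. By default both `is_a` and `part_of` edges
#' count as parent relations, the standard convention for Gene Ontology
#' hierarchy traversal; set `include_part_of = FALSE` to restrict to `is_a`.
#'
#' The parent graph is validated: every parent accession must refer to a
#' declared, non-obsolete term, and the graph must be acyclic. Roots are the
#' terms with no parents (GO has up to three: one per namespace).
#'
#' @param path path to an OBO file (plain or gzip) or a character vector of
#'   lines.
#' @param include_part_of logical; treat `relationship: part_of` as a parent
#'   edge (default `TRUE`).
#' @return an object of class `gota_ontology`: a list with `terms` (named
#'   list of term records), `parents` (named list of parent accessions),
#'   `roots`, and `anc`, the precomputed ancestor closure of every term
#'   (each closure includes the term itself).
#' @examples
#' obo <- c("[Term]", "id: GO:0000001", "name: root",
#'          "[Term]", "id: GO:0000002", "name: child", "is_a: GO:0000001")
#' onto <- parse_obo(obo)
#' onto$roots
#' @export
parse_obo <- function(path, include_part_of = TRUE) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(gzfile(path), warn = FALSE)
  } else {
    as.character(path)
  }
  lines <- sub("\\s+$", "", lines)

  # Split into stanzas; track line numbers for error reporting.
  stanza_starts <- grep("^\\[", lines)
  terms <- list()
  obsolete_ids <- character(0)
  for (si in seq_along(stanza_starts)) {
    start <- stanza_starts[si]
    if (lines[start] != "[Term]") next
    end <- if (si < length(stanza_starts)) stanza_starts[si + 1L] - 1L else length(lines)
    body <- lines[seq(start + 1L, end)]
    body <- body[nzchar(body)]
    hit <- regexpr("^([a-z_]+):\\s*", body)
    if (any(hit < 0)) {
      bad <- which(hit < 0)[1]
      stop("malformed OBO stanza at line ", start + bad, ": ", body[bad])
    }
    keys <- sub(":.*$", "", body)
    vals <- sub("^[a-z_]+:\\s*", "", body)

    rec <- list(
      id = NA_character_, name = "", synonyms = character(0),
      namespace = NA_character_, parents = character(0),
      description = "", obsolete = FALSE
    )
    for (j in seq_along(keys)) {
      key <- keys[j]; val <- vals[j]
      if (key == "id") {
        rec$id <- val
      } else if (key == "name") {
        rec$name <- val
      } else if (key == "namespace") {
        rec$namespace <- .abbrev_namespace(val)
      } else if (key == "synonym") {
        # synonym: "text" SCOPE [xrefs]
        m <- regmatches(val, regexpr('"[^"]*"', val))
        if (length(m)) rec$synonyms <- c(rec$synonyms, substr(m, 2L, nchar(m) - 1L))
      } else if (key == "def") {
        m <- regmatches(val, regexpr('"[^"]*"', val))
        rec$description <- if (length(m)) substr(m, 2L, nchar(m) - 1L) else val
      } else if (key == "is_a") {
        rec$parents <- c(rec$parents, sub("\\s*!.*$", "", val))
      } else if (key == "relationship" && include_part_of) {
        parts <- strsplit(sub("\\s*!.*$", "", val), "\\s+")[[1]]
        if (length(parts) >= 2L && parts[1] == "part_of") {
          rec$parents <- c(rec$parents, parts[2])
        }
      } else if (key == "is_obsolete") {
        rec$obsolete <- identical(tolower(val), "true")
      }
    }
    if (is.na(rec$id) || !nzchar(rec$id)) {
      stop("OBO [Term] stanza at line ", start, " has no id")
    }
    if (rec$obsolete) {
      obsolete_ids <- c(obsolete_ids, rec$id)
      next
    }
    rec$parents <- unique(rec$parents)
    terms[[rec$id]] <- rec
  }
  if (length(terms) == 0L) stop("no usable [Term] stanza found")

  ids <- names(terms)
  parents <- lapply(terms, function(t) t$parents)
  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing)) {
    stop("parent term(s) not declared or obsolete: ", paste(missing, collapse = ", "))
  }
  .validate_acyclic(parents)

  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  onto <- structure(
    list(terms = terms, parents = parents, roots = roots),
    class = "gota_ontology"
  )
  onto$anc <- .ancestor_closures(onto)
  onto
}

.abbrev_namespace <- function(ns) {
  switch(ns,
    biological_process = "BP",
    molecular_function = "MF",
    cellular_component = "CC",
    ns
  )
}

.validate_acyclic <- function(parents) {
  # Kahn's algorithm on child -> parent edges; leftovers indicate a cycle.
  indeg <- vapply(parents, length, integer(1))
  queue <- names(indeg)[indeg == 0L]
  children <- .invert_edges(parents)
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(parents)) stop("parent graph contains a cycle")
}

.invert_edges <- function(parents) {
  children <- stats::setNames(vector("list", length(parents)), names(parents))
  for (id in names(parents)) {
    for (pa in parents[[id]]) children[[pa]] <- c(children[[pa]], id)
  }
  children
}

.ancestor_closures <- function(onto) {
  # Closure of each term (including itself) in one topological pass.
  parents <- onto$parents
  order <- .topo_order(parents)
  anc <- stats::setNames(vector("list", length(parents)), names(parents))
  for (id in order) {
    up <- unlist(anc[parents[[id]]], use.names = FALSE)
    anc[[id]] <- unique(c(id, up))
  }
  anc
}

.topo_order <- function(parents) {
  # Parents before children.
  indeg <- vapply(parents, length, integer(1))
  children <- .invert_edges(parents)
  queue <- names(indeg)[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, id)
    for (ch in children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' @export
print.gota_ontology <- function(x, ...) {
  cat("gota ontology:", length(x$terms), "terms,",
      length(x$roots), "root(s)\n")
  ns <- table(vapply(x$terms, function(t) {
    if (is.na(t$namespace)) "unset" else t$namespace
  }, character(1)))
  cat("namespaces:", paste(names(ns), ns, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.check_terms_exist <- function(onto, x) {
  unknown <- setdiff(x, names(onto$terms))
  if (length(unknown)) {
    stop("unknown term accession(s): ", paste(unknown, collapse = ", "))
  }
}

#' Ancestor closure of a term set
#'
#' Returns the set `A(X)`: the input terms together with every term
#' reachable from them by following parent edges up to the root(s). By
#' convention the closure contains `X` itself, so `X` is always a subset of
#' the result and the result is closed under taking parents.
#'
#' @param onto a `gota_ontology`.
#' @param x character vector of term accessions.
#' @return character vector of accessions (unique, unordered).
#' @export
ancestors <- function(onto, x) {
  x <- unique(as.character(x))
  if (length(x) == 0L) return(character(0))
  .check_terms_exist(onto, x)
  unique(unlist(onto$anc[x], use.names = FALSE))
}

#' Leaf reduction of a term set
#'
#' Returns `L(X)`, the maximal antichain of `X`: the largest subset such
#' that no member is an ancestor of another member. Every removed term is a
#' proper ancestor of some kept term. Downstream information-theoretic
#' metrics average over `L(X)`, hence `x` must be non-empty.
#'
#' @inheritParams ancestors
#' @return character vector of accessions.
#' @export
leaves <- function(onto, x) {
  x <- unique(as.character(x))
  if (length(x) == 0L) stop("leaf reduction of an empty set is undefined")
  .check_terms_exist(onto, x)
  proper_anc <- unique(unlist(
    lapply(x, function(t) setdiff(onto$anc[[t]], t)),
    use.names = FALSE
  ))
  setdiff(x, proper_anc)
}

#' Information content of ontology terms
#'
#' Computes `ic(t) = -log Pr(t)` (natural log, nats) from a background
#' annotation set. By default `Pr(t)` is the fraction of publications whose
#' *ancestor-propagated* gold annotation set contains `t`; propagation
#' guarantees `Pr(root) = 1` (so roots get ic 0) and makes ic monotone
#' non-increasing towards the root, which the max-over-common-ancestors
#' Resnik similarity presupposes. `propagate = FALSE` counts direct
#' annotations only.
#'
#' Terms never observed in the background get the maximum observed ic (a
#' cap), so similarity computations never divide by zero or take the log of
#' zero.
#'
#' @param onto a `gota_ontology`.
#' @param gold a `gota_annotations` set (see [read_annotations()]).
#' @param propagate logical; propagate gold sets to ancestors before
#'   counting (default `TRUE`).
#' @return an object of class `gota_ic`: a named numeric vector of ic
#'   values covering every term in the ontology, with attribute `ic_max`.
#' @export
information_content <- function(onto, gold, propagate = TRUE) {
  stopifnot(inherits(gold, "gota_annotations"))
  if (length(gold) == 0L) stop("empty annotation set")
  counts <- stats::setNames(integer(length(onto$terms)), names(onto$terms))
  for (terms in gold) {
    eff <- if (propagate) ancestors(onto, terms) else unique(terms)
    counts[eff] <- counts[eff] + 1L
  }
  n <- length(gold)
  ic <- ifelse(counts > 0L, -log(counts / n), NA_real_)
  observed <- ic[!is.na(ic)]
  ic_max <- if (length(observed)) max(observed) else 0
  ic[is.na(ic)] <- ic_max
  structure(ic, ic_max = ic_max, class = "gota_ic")
}

#' @export
print.gota_ic <- function(x, ...) {
  cat("gota information-content table:", length(x), "terms, ic range [",
      format(min(x)), ",", format(max(x)), "]\n")
  invisible(x)
}

#' Resnik semantic similarity between two terms
#'
#' The maximum information content among the common ancestors of `t` and
#' `p` (both closures include the terms themselves, so
#' `resnik(t, t) = ic(t)`). Terms with no common ancestor — possible in a
#' multi-root ontology when the terms live in different namespaces — score
#' 0, the same value as a root-only overlap.
#'
#' @param onto a `gota_ontology`.
#' @param ict a `gota_ic` table from [information_content()].
#' @param t,p term accessions.
#' @return non-negative similarity in nats.
#' @export
resnik <- function(onto, ict, t, p) {
  .check_terms_exist(onto, c(t, p))
  common <- intersect(onto$anc[[t]], onto$anc[[p]])
  if (length(common) == 0L) return(0)
  max(unname(ict[common]))
}

#' Lin semantic similarity between two terms
#'
#' The normalized Resnik similarity,
#' `2 * resnik(t, p) / (ic(t) + ic(p))`, bounded in `[0, 1]` under the
#' default propagated-frequency information content. When both terms have
#' ic 0 (e.g. two roots) the similarity is defined as 0.
#'
#' @inheritParams resnik
#' @return similarity in `[0, 1]`.
#' @export
lin <- function(onto, ict, t, p) {
  denom <- unname(ict[t]) + unname(ict[p])
  if (denom == 0) return(0)
  2 * resnik(onto, ict, t, p) / denom
}
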