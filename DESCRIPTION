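Package: gota
Title: Gene Ontology Term Annotation of Biomedical Literature
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns Gene Ontology (GO) terms to biomedical publications by
    combining a k-nearest-neighbour publication similarity score with a
    direct term similarity re-weighting. Publications and GO terms are
    represented as tf-idf bags of words (plus weighted reference vectors
    and publication years); candidate terms are transferred from the most
    similar knowledge-base publications and re-weighted by direct
    query-term comparison. Ships the full hierarchical evaluation suite
    (reciprocal rank, recall at k, hierarchical precision and recall, CAFA
    threshold-swept F-max, information-theoretic precision and recall via
    Resnik/Lin semantic similarity), frequency- and information-content
    based naive baselines, readers for OBO, GAF, PubMed XML, TSV and JSONL
    inputs, and a seeded synthetic-data generator for end-to-end testing
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
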