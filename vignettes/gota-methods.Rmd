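---
title: "Annotating biomedical literature with GO terms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating biomedical literature with GO terms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gota)
```

## The problem

Database curators extract Gene Ontology (GO) annotations from scientific
publications by hand. A useful assistant ranks, for a given paper (or any
fragment of biomedical text), a short list of GO terms that cover its
biological content. This is an extreme hierarchical multi-label problem:
tens of thousands of candidate terms arranged in three DAGs (biological
process, molecular function, cellular component), with most papers
carrying only a handful of gold annotations.

`gota` approaches it with two complementary comparisons combined into a
single relatedness score between a query $q$ and a term $t$:

$$\Phi(q,t) = \Phi_P(q,t)\,\cdot\,\Phi_T(q,t)$$

* **Publication-centric** $\Phi_P$: a k-nearest-neighbour transfer. The
  query is compared against every publication in an annotated knowledge
  base (KB); the gold annotations of the top-$K$ most similar
  publications are transferred to the query, each weighted by its
  publication similarity. Only terms annotated to some KB publication can
  be proposed.
* **Term-centric** $\Phi_T$: a direct comparison between the query and
  each candidate term's own textual profile, used as a re-weighting of
  the transferred candidates.

## Features and scores

Publications are represented by four features: $\mathcal W(p)$, a tf-idf
bag of words over title + abstract; $\mathcal T(p)$ over the title alone;
$\mathcal R(p)$, an idf-weighted vector of cited PMIDs; and the year
$\mathcal Y(p)$. Terms get $\mathcal W(t)$ (name, synonyms, description,
plus the title/abstract of every KB publication *directly* annotated with
the term), $\mathcal T(t)$ (name + synonyms) and $\mathcal Y(t)$ (mean
year of annotating publications).

The publication comparison score is a product of per-feature
similarities, each in $[0,1]$:

$$\phi_P(q,p) = \prod_{i=1}^4 (1+f_i(q,p))^{m_i}$$

with $f_1,f_2,f_3$ cosine similarities of the $\mathcal W$, $\mathcal T$
and $\mathcal R$ vectors and $f_4 = (50-|\Delta Y|)/50$ (0 beyond 50
years). The $1+f$ form makes a missing feature (no title, no
bibliography, no year — each then 0) a *neutral factor*: partial records
are compared on whatever they do have. $\Phi_P(q,t)$ sums $\phi_P(q,p)$
over the top-$K$ neighbours directly annotated with $t$.

The term comparison score has the same form over five features,

$$\Phi_T(q,t) = \prod_{i=1}^5 (1+g_i(q,t))^{n_i},$$

with $g_1, g_2$ cosines against the term's $\mathcal W/\mathcal T$ bags,
$g_3$ the fraction of the term's name/synonym stems present in the
query's bag, $g_4 = \min(c,4)/4$ for $c$ literal (pre-stemming,
case-insensitive) occurrences of the term name or synonyms in the query
text, and $g_5$ the year proximity.

### Parameters

| parameter | default | meaning |
|---|---|---|
| $m$ | (4, 1, 3, 1) | exponent weights of $f_1..f_4$ |
| $n$ | (4, 1, 2, 1, 1) | exponent weights of $g_1..g_5$ |
| $K$ | 150 | neighbours whose annotations transfer |

The defaults are the tuned optimum on a large PubMed/GOA benchmark; the
exponents balance features whose raw values follow quite different
distributions rather than expressing importance directly. Sensible $K$
ranges from 50 to 300. An exponent of 0 switches a feature off
(`gota_params()` warns above 4, the tuned grid's ceiling). For raw-text
queries only $f_1$ (and $g_1,g_3,g_4$) can be non-zero, so the method
degrades gracefully to pure text comparison.

## Text preprocessing choices

Tokenization lowercases, splits on non-alphanumerics (so `p53` survives),
drops one-character tokens and stopwords, and Porter-stems the rest. The
stemmer is a from-scratch implementation of the classic algorithm
(verified against its canonical published examples) because no stemming
library is available as a dependency. The shipped stopword list is a
standard English list; it is a configurable argument everywhere.

Numerical conventions, fixed and documented rather than tunable:

* **idf document pool.** Word idf is fitted over publications *and* term
  texts together: $\mathrm{idf}(w) = \ln(N/\mathrm{df}(w))$ with $N$ =
  #publications + #terms. Reference idf uses only publications with a
  bibliography.
* **Logarithms** are natural throughout (idf and information content).
  Cosine is scale-invariant per vector but idf acts per dimension, so the
  base is fixed rather than configurable.
* **tf denominator**: token count *after* stopword removal and stemming.
  Out-of-vocabulary query tokens are dropped from the vector (they cannot
  match any KB dimension) but still count in the denominator.
* **Term indexing** uses direct annotations only; ancestor propagation at
  indexing time is available behind a flag but off by default, matching
  the reading that a term's text is the text of publications associated
  with *that* term.
* **Year averaging** for $\mathcal Y(t)$: arithmetic mean rounded to the
  nearest integer before the year-distance feature.
* **Tie-breaks**: every ranking (neighbours, terms) sorts descending by
  score then ascending by identifier, so runs are bit-reproducible.
* **Leave-one-out**: when a query's pmid exists in the KB it is excluded
  from the neighbour scan by default — honest evaluation on held-in
  documents.

## Information content and similarity

$\mathrm{ic}(t) = -\ln \Pr(t)$ with $\Pr(t)$ the fraction of KB documents
whose *ancestor-propagated* gold set contains $t$. Propagation guarantees
$\Pr(\mathrm{root})=1$ (ic 0) and monotone ic along the hierarchy, which
the max-over-common-ancestors Resnik similarity presupposes; a raw-count
mode exists behind a flag. Terms unobserved in the background get the
maximum observed ic as a cap, so Lin similarity
$2\,\mathrm{sim}_{Resnik}/(\mathrm{ic}(t)+\mathrm{ic}(p))$ never divides
by zero; terms in different namespaces (no common ancestor) score 0.

## Evaluation metrics

For gold set $T$ and ranked prediction $P$ (top-$k$ prefix $P_k$,
score-threshold subset $P_s$):

* $RR_k$ and $R_k$: reciprocal rank of the first hit and the recovered
  fraction of $T$, both within the top $k$ (defaults focus on $k=10$).
* $hP_k, hR_k, hF_k$: precision/recall on ancestor closures
  $\mathcal A(\cdot)$, combined by the harmonic mean. $hP$ is knowingly
  fooled by generic predictions (a root-only prediction scores
  $hP = 1$), which the tests assert as a *feature* of the metric suite.
* $hF_{max}$: CAFA-style; sweep thresholds $s$, average $hP_s$ over
  non-empty predictions and $hR_s$ over all pairs, report the maximum
  harmonic mean. The sweep runs over the observed score set (plus each
  score as its own threshold), which attains the exact maximum with
  finite work — the dataset-level averages only change at observed
  scores.
* $iP_k, iR_k$: leaf-reduce both sets ($\mathcal L(\cdot)$, the maximal
  antichain), then average each side's best Lin similarity against the
  other. Reported defaults are $iP_1$ and $iR_{10}$.

One printed-formula wrinkle: the hierarchical F-measure is implemented as
the harmonic mean $2\,hP\,hR/(hP+hR)$; a denominator reading "$hP + hP$"
in the source formula is treated as a typo.

The two baselines replicate the naive predictors used for context:
`baseline_randfr()` ranks terms by KB annotation frequency and
`baseline_randic()` by mean information-theoretic precision against all
KB gold sets; both return the same ranking for every query.

## The synthetic benchmark

`synth_generate()` states a small world with the statistical structure
the method assumes, so the whole pipeline is testable offline:

* a layered random DAG (default 50 terms, depth 4, 1–2 parents each);
* disjoint per-term signal vocabularies (default 20 words) over a
  background noise vocabulary (200 words). Disjointness is a deliberate
  idealization: it separates "the method fails" from "the data is
  ambiguous" when a planted-recovery test goes red;
* per-document gold-term counts drawn from a skewed distribution
  matching literature-derived annotation sets (39% singletons,
  essentially all ≤ 10);
* titles that are 90% signal words of the document's gold terms —
  mirroring the observation that the title is the strongest signal —
  abstracts mixing signal and noise at `noise_rate` (default 0.5),
  uniform years, and citations preferentially to KB documents sharing
  the document's primary term;
* a held-out query set disjoint from the KB, and a single RNG stream per
  seed (byte-identical regeneration).

What the generator does **not** emulate: natural-language syntax,
polysemy and shared vocabulary between related terms, realistic citation
topology, or the annotation biases of curated corpora. A green
planted-recovery test therefore establishes that the scoring machinery
ranks the planted signal above frequency/ic baselines under heavy noise —
not that real-literature accuracy matches any published figure.

## Degenerate inputs and errors

Publications must have a non-empty title or abstract; queries that
tokenize to nothing in-vocabulary raise `"no usable text"` rather than
returning an empty ranking. Empty gold sets are errors in every metric
(several denominators are $|T|$ or $|\mathcal L(T)|$). Annotation pairs
with unknown/obsolete terms or missing publication records are dropped
with a message at KB build time; an empty KB after validation is an
error. Obsolete OBO terms are excluded at parse time, and a parent
reference to an undeclared (or obsolete) term, or a cyclic parent graph,
fails validation.

## Known limitations

* The confidence-tier filter (low/medium/high) of the original web tool
  is not implemented; the raw $\Phi$ score is exposed instead.
* The neighbour scan is exhaustive (sparse matrix-vector products); no
  approximate nearest-neighbour index. Fine at desk scale, untested at
  hundreds of thousands of documents.
* `evaluate()`'s per-namespace breakdown truncates predictions to the
  namespace before ranking; by default evaluation runs over the entire
  hierarchy.
* Whether $g_4$'s occurrence count should sum over synonyms or take a
  per-phrase maximum is unspecified in the method's description; this
  implementation sums.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
b <- synth_generate(synth_config(seed = 7, n_pubs = 120, n_test = 20))
idx <- build_index(b$kb, b$onto)
ict <- information_content(b$onto, b$kb$gold)

pred <- gota_predict(b$test_pubs[[1]], idx)
head(pred$ranked, 3)

ds <- lapply(names(b$test_pubs), function(pm) {
  list(gold = b$test_gold[[pm]], pred = gota_predict(b$test_pubs[[pm]], idx))
})
evaluate(b$onto, ict, ds)$summary
```

The same pipeline, at the stated benchmark scale (500 KB documents, 100
queries, noise 0.5), is what `scripts/acceptance.R` runs end to end.
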