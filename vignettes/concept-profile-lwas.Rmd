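---
title: "Concept-profile literature-wide association studies with litwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-profile literature-wide association studies with litwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litwas)
```

## The model

litwas implements a literature-wide association study (LWAS): a scan of
every gene x disease pair in a controlled vocabulary for evidence of
association carried by the scientific literature, including pairs that
have never been mentioned together. The method follows the Swanson
A-B-C idea of literature-based discovery: if one body of literature
links gene *X* to intermediate concepts *Y1...Yk*, and a disjoint body
links those same intermediates to disease *Z*, the X-Z relation is
*implicit* even though no single abstract states it.

The pipeline has three stages.

**1. Indexing.** Each document (title + abstract + keyword fields) is
normalized — lowercased, punctuation stripped, stop words removed,
tokens stemmed — and tagged by longest-match dictionary lookup against
the thesaurus. Occurrence is presence-based: a concept either occurs in
a document or it does not, so the whole corpus reduces to a sparse
binary incidence matrix (concepts x documents). A term naming several
concepts (a homonym) tags all of them, each flagged ambiguous; this
mirrors how a dictionary tagger without contextual disambiguation
behaves, and a `skipAmbiguous` switch drops such tags instead.

**2. Concept profiles.** For a seed concept $x$, every concept $y$
co-occurring with it in at least one document receives a weight: the
symmetric uncertainty coefficient of the two binary per-document
occurrence indicators,

$$U(x, y) = \frac{2\,[H(X) + H(Y) - H(X,Y)]}{H(X) + H(Y)}
          = \frac{2\,I(X;Y)}{H(X)+H(Y)} \in [0, 1],$$

computed from the 2x2 contingency table (both / first only / second
only / neither) with entropies in bits and $0 \log 0 := 0$. The log
base cancels in the ratio. $U$ is normalized mutual information: it
discounts ubiquitous concepts (a concept present in nearly every
document has near-zero entropy and so near-zero weight, the "human"
problem) and rewards specific associations, which is what makes match
scores comparable across well-studied and rarely-studied concepts. The
profile of $x$ is the sparse vector of these weights; the seed itself
is included with weight 1 (its indicator is identical to itself), so
endpoint concepts participate in profile overlaps — this is why, for an
explicit pair, the partner concept itself often tops the
connecting-concept list.

Two conventions matter and are deliberate:

- **Profiles contain only co-occurring concepts.** Mutual information
  is also positive for *anti*-correlated pairs, but profile links model
  explicit co-occurrence, so $n_{11} = 0$ yields weight 0. This also
  bounds profile size by the seed's document neighborhood.
- **The 5-abstract cutoff.** Seeds appearing in fewer than `minDocs`
  (default 5) documents get no profile: below that, the contingency
  statistics are noise. Pairs with a missing profile on either side are
  *unbuildable* and counted separately, never scored.

**3. Matching.** The match score of gene $g$ and disease $d$ is the
plain inner product of their profiles over shared concepts — no cosine
or length normalization, so both the number and the weights of shared
concepts contribute. Each shared concept's contribution is
$100 \cdot w_g(y) w_d(y) / \mathrm{score}$ percent; contributions sum
to 100 and are reported ranked, which is how an association is
rationalized for a reviewer. Pairs co-occurring in at least one
abstract are *explicit* (their shared documents are the evidence);
everything else with positive score is *implicit*. Scores are
normalized to a percentile rank, either against the full ensemble of
scored pairs or against a seeded random reference sample (default size
1500) when incremental scoring must be projected onto a fixed scale.

## Numerical and procedural choices

- **Percentile tie rule.** `percentileRank` uses the strictly-below
  convention: $100 \cdot \#\{r < s\}/|R|$. A score equal to every
  reference value ranks 0. The rule is documented because ties are
  common at score 0 in sparse corpora; any consistent rule works, this
  one never overstates a rank.
- **Tie-breaking.** All rankings (candidates, connecting concepts,
  abundance lists) break score ties lexicographically by concept id, so
  output is reproducible to the byte.
- **Stemming.** A deterministic suffix stemmer (strip
  ing/ed/ies/es/s/e, longest first, iterated to a fixed point, minimum
  stem length 3, tokens containing digits untouched) stands in for a
  full lexical normalizer. Iterating to a fixed point makes
  normalization idempotent. An identity stemmer is available for
  corpora where stemming is undesirable. The stemmer and stop-word list
  are recorded in the thesaurus object so documents are normalized
  exactly as the vocabulary was.
- **Degenerate inputs.** A contingency with zero total is a domain
  error; $H(X)+H(Y)=0$ (a concept in all or none of the documents)
  returns 0; computed $U$ is clamped to $[0,1]$ against floating-point
  drift. Empty corpora, empty profiles and header-only stores are all
  legal and round-trip.
- **Monotonicity caveat.** With both margins fixed, moving mass onto
  the diagonal ($n_{11}{+}1, n_{10}{-}1, n_{01}{-}1, n_{00}{+}1$) does
  not decrease $U$ *in the positively-associated regime*
  ($n_{11} \ge$ its independence expectation). Below independence the
  table is anti-correlated and $U$ falls as $n_{11}$ rises toward
  independence — $U$ measures dependence of either sign. The property
  suite tests the regime where the claim is true.

## The GWAS-overlap analysis

`filterHits` reduces an external hit table (gene symbol, trait
description, p-value) to pairs an LWAS can say something new about, in
six audited steps: drop previously reported pairs; drop "response
(to)" pharmacogenomic traits; keep only records unambiguously mappable
to exactly one gene and one disease concept (when several candidates
share the normalized term, a unique case-sensitive match decides;
otherwise the record is dropped and logged); drop explicit pairs; drop
pairs without profiles; deduplicate keeping the smallest p-value. The
removal ledger reports each step's count, and the counts sum to input
minus survivors by construction. Significance classes follow the usual
GWAS conventions (high: $p < 10^{-8}$; intermediate:
$10^{-8} \le p < 10^{-5}$). Enrichment above a percentile cutoff $c$ is
$\mathrm{pass\%} / (100 - c)$, the fold over the uniform expectation.

## Nanopublications

Each association is published as a nanopublication: four named RDF
graphs (head, assertion, provenance, publication info). The default
implicit-association layout totals exactly 20 triples: head 4 (the
nanopub typed and linked to its three parts), assertion 7 (a typed
association node referring to gene and disease URIs and to a typed
percentile value), provenance 4 (a typed generating activity and the
corpus snapshot used), publication info 5 (created, creator, license,
version, creating tool). Gene and disease URIs are built from each
concept's first cross-reference through a configurable prefix table
(EG, OMIM, UMLS, GO, MeSH by default); a concept without
cross-references falls back to a package-local concept URI, and an
unknown prefix is a configuration error rather than a silent guess.
Explicit-pair nanopublications assert one co-occurrence per evidence
document. Predicate URIs lean on SIO, PROV-O, DCTerms and PAV plus a
small package namespace, and every term is remappable via
`nanopubVocab()` — the table documents this package's choices without
claiming fidelity to any particular upstream schema. Serialization
(TriG or N-Quads) is canonical and deterministic; URIs are pure
functions of (run id, pair, document), so minting is injective per run.
Content-hash (trusty) URIs are out of scope.

## What the synthetic generator emulates — and what it does not

`generateCorpus` builds a corpus from a `synthSpec`: for each planted
bridge $(g, y, d)$, `docsPerLink` documents mention $\{g, y\}$ and a
disjoint `docsPerLink` mention $\{y, d\}$; planted explicit pairs get
documents mentioning both endpoints; background concepts follow a Zipf
abundance law (exponent 1.1 by default, the skew regime typical of
concept usage in bibliographic corpora) and supply noise mentions.
Noise draws only background concepts, so no noise level can create an
unplanted gene-disease co-occurrence — the implicit/explicit ground
truth is exact at any `noiseRate`. Homonymy is emulated by giving
background-concept pairs a shared synonym that is counted by the
homonym statistics but never emitted into documents.

The reference conditions are the generator defaults: 12 genes x 8
diseases, 10 bridges, 2 explicit pairs, 100 background concepts, 5
documents per link (matching the profile cutoff), noise 0.05, seed 42
— about 310 documents, small enough that the full pipeline runs in
seconds yet large enough that every stage is exercised. Documents are
bags of collision-free surface forms joined into pseudo-sentences; the
generator makes no attempt at natural language, citation dynamics, or
realistic nomenclature. Passing tests therefore demonstrate the
*counting and scoring machinery* — tagging, contingencies, weighting,
matching, ranking, publishing — not recognition performance on real
prose, where term ambiguity and variant spelling dominate errors. The
corpus-scale figures a real deployment produces (median profile sizes
in the thousands, hundreds of millions of pairs) require a licensed
bibliographic corpus and are outside what desk-scale validation can
reproduce; the arithmetic identities those figures obey are checked
exactly instead.

`evaluateRecovery` scores the planted structure: for each bridge, the
disease's rank among all diseases for that gene, and whether the pair's
percentile beats the median percentile of *unbridged* pairs (scored
pairs that are neither planted bridges nor planted explicit pairs —
planted explicit pairs are excluded from the baseline because they are
positives of the other kind). At the reference conditions recovery is
complete: every bridged pair is implicit (no co-occurrence anywhere),
scores above zero, and outranks the unbridged median.

## Known limitations

- Dictionary tagging has no contextual disambiguation; homonyms tag
  every candidate concept by design, and downstream users must treat
  ambiguous tags accordingly.
- The tagger is exact-match after normalization: spelling variants not
  in the thesaurus are missed.
- Full-ensemble percentiles are quadratic in concept counts; the
  sampled-reference mode exists for corpora where the full ensemble is
  impractical.
- The suffix stemmer is intentionally crude; for real corpora a
  domain-tuned normalizer will change tag boundaries (but not any
  downstream arithmetic).

## A worked run

```{r pipeline}
g <- generateCorpus(demoSynthSpec())
idx <- buildConceptIndex(g$corpus, g$thesaurus)
run <- runLwas(idx, g$thesaurus)
run
rankCandidates(run, "D01", topN = 4)[
  , c("rank", "concept_id", "score", "percentile", "explicit",
      "top_connecting_concept")]
```

The explicit causative gene ranks first with its partner as top
connecting concept; the three bridged genes follow as implicit
associations connected through the planted bridge concept. With only
four scored pairs the percentile scale is coarse — on the default
reference spec (96 pairs) bridged pairs land near the 90th percentile
while unbridged pairs sit at 0.
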