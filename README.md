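# litwas

Literature-wide association studies (LWAS) from concept co-occurrence
profiles.

Most gene-disease relations that the literature supports are never
stated in any single abstract. `litwas` finds them the Swanson A-B-C
way: if one set of abstracts links gene *X* to intermediate concepts
*Y1...Yk* and a disjoint set links those intermediates to disease *Z*,
the X-Z association is *implicit* and can be scored. The package is
aimed at text-mining and knowledge-graph practitioners who want the
full pipeline — thesaurus, tagger, index, weighting, matching, ranking,
enrichment, publishing — as composable R functions with an auditable
synthetic test bed.

## Method in brief

1. **Index**: documents are normalized (lowercase, stop words removed,
   suffix stemming) and tagged by longest-match dictionary lookup
   against a typed thesaurus; the corpus becomes a sparse binary
   concept x document incidence matrix.
2. **Profiles**: for seed concept *x*, every co-occurring concept *y*
   is weighted by the symmetric uncertainty coefficient of the two
   binary occurrence indicators,
   `U = 2·I(X;Y) / (H(X)+H(Y)) ∈ [0,1]`, computed from the 2x2
   per-abstract contingency table. Seeds in fewer than 5 abstracts get
   no profile.
3. **Match**: the association score of a gene-disease pair is the
   inner product of their profiles over shared (connecting) concepts;
   each connecting concept's share of the score rationalizes the
   association. Pairs co-occurring in an abstract are *explicit*;
   scored pairs that never co-occur are *implicit*. Scores are
   percentile-ranked (strictly-below convention) against the full
   ensemble or a seeded 1500-pair reference sample.
4. **Compare & publish**: external GWAS-style hit tables pass a
   six-step audited filter; hits are checked for fold enrichment above
   a percentile cutoff (`pass% / (100 − cutoff)`); associations export
   as CSV and as nanopublications — four named RDF graphs per
   association, 20 triples in the default implicit layout — in TriG or
   N-Quads.

## Worked example

A miniature disease scenario: one disease, one causative gene with
explicit literature links, three genes connected only through a shared
bridge concept, plus a noisy Zipf background.

```r
library(litwas)

g   <- generateCorpus(demoSynthSpec())          # corpus + thesaurus + truth
idx <- buildConceptIndex(g$corpus, g$thesaurus)
run <- runLwas(idx, g$thesaurus)
run
#> LwasRun: 4 possible pairs; 4 scored; 0 unbuildable
#>   explicit: 1 (25.00%)

rankCandidates(run, "D01", topN = 4)[
  , c("rank", "concept_id", "score", "percentile", "explicit",
      "top_connecting_concept")]
#>   rank concept_id  score percentile explicit top_connecting_concept
#> 1    1        G01 0.5058         75     TRUE                    D01
#> 2    2        G02 0.0364          0    FALSE                    Y01
#> 3    3        G03 0.0364          0    FALSE                    Y01
#> 4    4        G04 0.0364          0    FALSE                    Y01
```

The explicit causative gene `G01` ranks first (its partner concept is
itself the strongest connector, as expected when endpoints carry
self-weight 1). The three bridged genes follow as implicit hits, each
connected through the planted bridge `Y01`:

```r
connectingConcepts(buildProfile(idx, "G02"), buildProfile(idx, "D01"))
#>   rank concept_id weight_a weight_b contribution_pct
#> 1    1        Y01    0.163    0.224              100
```

100% of `G02`'s match to the disease flows through the bridge concept
— exactly the rationalization an analyst needs when triaging an
implicit hit. See `vignettes/concept-profile-lwas.Rmd` for the model,
conventions and limitations.

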