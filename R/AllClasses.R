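#' @importClassesFrom Matrix dgCMatrix
NULL

setOldClass("Date")

## ---------------------------------------------------------------------------
## Contingency
## ---------------------------------------------------------------------------

#' 2x2 abstract-level co-occurrence table for a concept pair
#'
#' Cell counts of per-document presence of two concepts: both (\code{n11}),
#' first only (\code{n10}), second only (\code{n01}), neither (\code{n00}).
#' The four cells sum to the corpus size.
#'
#' @slot n11,n10,n01,n00 nonnegative counts.
#' @export
setClass("Contingency",
  representation(n11 = "numeric", n10 = "numeric",
                 n01 = "numeric", n00 = "numeric"))

setValidity("Contingency", function(object) {
  cells <- c(object@n11, object@n10, object@n01, object@n00)
  if (length(cells) != 4L || anyNA(cells))
    return("all four cells must be single non-missing numbers")
  if (any(cells < 0)) return("cell counts must be nonnegative")
  if (any(cells != floor(cells))) return("cell counts must be whole numbers")
  TRUE
})

#' @param n11,n10,n01,n00 nonnegative integer cell counts.
#' @return a \linkS4class{Contingency}.
#' @rdname Contingency-class
#' @export
#' @examples
#' Contingency(5, 5, 5, 85)
Contingency <- function(n11, n10, n01, n00) {
  new("Contingency", n11 = as.numeric(n11), n10 = as.numeric(n10),
      n01 = as.numeric(n01), n00 = as.numeric(n00))
}

setMethod("show", "Contingency", function(object) {
  m <- matrix(c(object@n11, object@n10, object@n01, object@n00), 2, 2,
              byrow = TRUE,
              dimnames = list(c("x=1", "x=0"), c("y=1", "y=0")))
  cat("Contingency (n =", sum(m), ")\n")
  print(m)
})

#' @export
setMethod("nDocs", "Contingency", function(x)
  x@n11 + x@n10 + x@n01 + x@n00)

## ---------------------------------------------------------------------------
## ConceptThesaurus
## ---------------------------------------------------------------------------

#' Controlled vocabulary of typed concepts with synonyms
#'
#' Holds one row per concept (id, preferred name, semantic type, xrefs), the
#' full synonym table, and a map from normalized terms to the concept ids
#' they denote.  A normalized term shared by several concepts is a homonym;
#' tagging emits all candidates.
#'
#' @slot concepts data.frame with columns \code{concept_id},
#'   \code{preferred_name}, \code{semantic_type} (gene/disease/other),
#'   \code{xrefs} (pipe-separated, may be empty).
#' @slot terms data.frame with columns \code{concept_id}, \code{term},
#'   \code{is_preferred}, \code{norm} (the normalized form used for lookup).
#' @slot termMap named list: normalized term -> character vector of
#'   concept ids.
#' @slot stopwords character vector used during normalization.
#' @slot stemmer name of the stemmer used ("suffix" or "identity").
#' @export
setClass("ConceptThesaurus",
  representation(concepts = "data.frame", terms = "data.frame",
                 termMap = "list", stopwords = "character",
                 stemmer = "character"))

setValidity("ConceptThesaurus", function(object) {
  cn <- colnames(object@concepts)
  need <- c("concept_id", "preferred_name", "semantic_type", "xrefs")
  if (!all(need %in% cn))
    return(paste("concepts must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@concepts$concept_id))
    return("concept_id must be unique")
  bad <- setdiff(unique(object@concepts$semantic_type),
                 c("gene", "disease", "other"))
  if (length(bad))
    return(paste("unknown semantic_type:", paste(bad, collapse = ", ")))
  if (nrow(object@concepts) &&
      !all(object@terms$concept_id %in% object@concepts$concept_id))
    return("terms reference unknown concept ids")
  ## every synonym resolves back to its concept through termMap
  if (nrow(object@terms)) {
    hit <- mapply(function(nrm, id) id %in% object@termMap[[nrm]],
                  object@terms$norm, object@terms$concept_id)
    if (!all(hit)) return("termMap does not cover all synonyms")
  }
  TRUE
})

setMethod("show", "ConceptThesaurus", function(object) {
  tab <- table(factor(object@concepts$semantic_type,
                      levels = c("gene", "disease", "other")))
  cat("ConceptThesaurus:", nrow(object@concepts), "concepts (",
      tab[["gene"]], "genes,", tab[["disease"]], "diseases,",
      tab[["other"]], "other );",
      length(object@termMap), "normalized terms; stemmer =",
      object@stemmer, "\n")
})

#' @export
setMethod("conceptIds", "ConceptThesaurus", function(x, ...)
  x@concepts$concept_id)

#' @export
setMethod("nConcepts", "ConceptThesaurus", function(x, ...)
  nrow(x@concepts))

#' Semantic types of thesaurus concepts
#' @param x a \linkS4class{ConceptThesaurus}.
#' @param ... unused.
#' @return named character vector concept_id -> semantic type.
#' @export
setMethod("semanticTypes", "ConceptThesaurus", function(x, ...)
  structure(x@concepts$semantic_type, names = x@concepts$concept_id))

## ---------------------------------------------------------------------------
## ConceptIndex
## ---------------------------------------------------------------------------

#' Bidirectional concept-document index
#'
#' Sparse binary incidence matrix (concepts x documents) over a tagged
#' corpus; the source of all co-occurrence contingencies.  Rows cover the
#' whole thesaurus so unindexed concepts have document frequency zero.
#'
#' @slot incidence dgCMatrix of 0/1 values, dimnames = (concept ids,
#'   doc ids).
#' @slot dates per-document dates (Date, NA when unknown), parallel to
#'   columns.
#' @slot ambiguousTags data.frame (doc_id, concept_id) of tags produced by
#'   a homonymous term.
#' @export
setClass("ConceptIndex",
  representation(incidence = "dgCMatrix", dates = "Date",
                 ambiguousTags = "data.frame"))

setValidity("ConceptIndex", function(object) {
  if (is.null(rownames(object@incidence)) && nrow(object@incidence) > 0)
    return("incidence needs concept ids as rownames")
  if (length(object@dates) != ncol(object@incidence))
    return("dates must parallel documents")
  v <- object@incidence@x
  if (length(v) && !all(v == 1)) return("incidence must be binary")
  TRUE
})

setMethod("show", "ConceptIndex", function(object) {
  cat("ConceptIndex:", ncol(object@incidence), "documents,",
      sum(Matrix::rowSums(object@incidence) > 0), "of",
      nrow(object@incidence), "concepts indexed,",
      length(object@incidence@x), "tags\n")
})

#' @export
setMethod("conceptIds", "ConceptIndex", function(x, ...)
  rownames(x@incidence))

#' @export
setMethod("docIds", "ConceptIndex", function(x, ...)
  colnames(x@incidence))

#' @export
setMethod("nDocs", "ConceptIndex", function(x, ...)
  ncol(x@incidence))

## ---------------------------------------------------------------------------
## ConceptProfile
## ---------------------------------------------------------------------------

#' Sparse weighted concept profile of a seed concept
#'
#' Weight vector over thesaurus concepts for one seed: each concept that
#' co-occurs with the seed in at least one document carries its symmetric
#' uncertainty weight; zero weights are not stored.  The seed itself is a
#' member with weight 1.
#'
#' @slot seed concept id of the seed.
#' @slot weights named numeric, all > 0, names sorted.
#' @slot builtFromNDocs corpus size the profile was computed from.
#' @slot minDocs document-frequency threshold in force when built.
#' @export
setClass("ConceptProfile",
  representation(seed = "character", weights = "numeric",
                 builtFromNDocs = "numeric", minDocs = "numeric"))

setValidity("ConceptProfile", function(object) {
  w <- object@weights
  if (length(w) && (is.null(names(w)) || any(!nzchar(names(w)))))
    return("weights must be named by concept id")
  if (any(w <= 0)) return("stored weights must be positive")
  if (any(w > 1 + 1e-12)) return("weights cannot exceed 1")
  if (is.unsorted(names(w))) return("weights must be sorted by concept id")
  TRUE
})

setMethod("show", "ConceptProfile", function(object) {
  cat("ConceptProfile for", object@seed, ":", length(object@weights),
      "weighted concepts (corpus n =", object@builtFromNDocs,
      ", min_docs =", object@minDocs, ")\n")
  if (length(object@weights)) {
    top <- head(sort(object@weights, decreasing = TRUE), 5L)
    for (i in seq_along(top))
      cat(sprintf("  %-20s %.4f\n", names(top)[i], top[i]))
  }
})

#' @export
setMethod("seedConcept", "ConceptProfile", function(x) x@seed)

#' @export
setMethod("profileWeights", "ConceptProfile", function(x) x@weights)

#' Number of nonzero entries in a concept profile
#' @param x a \linkS4class{ConceptProfile}.
#' @export
setMethod("profileSize", "ConceptProfile", function(x) length(x@weights))

## ---------------------------------------------------------------------------
## LwasRun
## ---------------------------------------------------------------------------

#' Result container of a full gene x disease LWAS
#'
#' @slot results data.frame with one row per scored pair: gene_id,
#'   disease_id, score, n_overlap, explicit, n_cooccurrences, percentile.
#' @slot profiles named list of \linkS4class{ConceptProfile} used.
#' @slot index the \linkS4class{ConceptIndex} scored against (or NULL for
#'   count-only runs).
#' @slot thesaurus the \linkS4class{ConceptThesaurus} (or NULL).
#' @slot pairsTotal genes x diseases in the thesaurus.
#' @slot pairsScored pairs with a profile on both sides.
#' @slot pairsUnbuildable pairsTotal - pairsScored.
#' @slot nExplicit scored pairs with at least one co-occurrence.
#' @slot config list snapshot: min_docs, percentile_mode, reference_size,
#'   until, seed, n_docs.
#' @export
setClass("LwasRun",
  representation(results = "data.frame", profiles = "list",
                 index = "ANY", thesaurus = "ANY",
                 pairsTotal = "numeric", pairsScored = "numeric",
                 pairsUnbuildable = "numeric", nExplicit = "numeric",
                 config = "list"))

setValidity("LwasRun", function(object) {
  if (object@pairsTotal < 0 || object@pairsScored < 0)
    return("pair counts must be nonnegative")
  if (object@pairsUnbuildable != object@pairsTotal - object@pairsScored)
    return("pairsUnbuildable must equal pairsTotal - pairsScored")
  if (!is.na(object@nExplicit) && object@nExplicit > object@pairsScored)
    return("nExplicit cannot exceed pairsScored")
  TRUE
})

#' Construct an LwasRun from explicit counts
#'
#' Used by \code{\link{runLwas}} and directly when only the counting
#' arithmetic is needed (e.g. projecting published corpus-level counts
#' through \code{\link{explicitFraction}}).
#'
#' @param nGenes,nDiseases thesaurus counts defining the pair universe.
#' @param pairsScored number of pairs with profiles on both sides.
#' @param nExplicit number of scored pairs with a co-occurrence.
#' @param results,profiles,index,thesaurus,config optional payload.
#' @return an \linkS4class{LwasRun}.
#' @export
#' @examples
#' r <- LwasRun(nGenes = 3, nDiseases = 4, pairsScored = 8, nExplicit = 2)
#' explicitFraction(r)
LwasRun <- function(nGenes, nDiseases, pairsScored,
                    nExplicit = NA_real_, results = data.frame(),
                    profiles = list(), index = NULL, thesaurus = NULL,
                    config = list()) {
  total <- as.numeric(nGenes) * as.numeric(nDiseases)
  new("LwasRun", results = results, profiles = profiles, index = index,
      thesaurus = thesaurus, pairsTotal = total,
      pairsScored = as.numeric(pairsScored),
      pairsUnbuildable = total - as.numeric(pairsScored),
      nExplicit = as.numeric(nExplicit), config = config)
}

setMethod("show", "LwasRun", function(object) {
  cat("LwasRun:", format(object@pairsTotal, big.mark = ","),
      "possible pairs;", format(object@pairsScored, big.mark = ","),
      "scored;", format(object@pairsUnbuildable, big.mark = ","),
      "unbuildable\n")
  if (!is.na(object@nExplicit)) {
    ef <- explicitFraction(object)
    cat(sprintf("  explicit: %s (%.2f%%)\n",
                format(ef[["n_explicit"]], big.mark = ","),
                ef[["fraction_pct"]]))
  }
})

#' @export
setMethod("lwasResults", "LwasRun", function(x) x@results)

#' @export
setMethod("lwasConfig", "LwasRun", function(x) x@config)

## ---------------------------------------------------------------------------
## Nanopub
## ---------------------------------------------------------------------------

#' A nanopublication: four named RDF graphs
#'
#' Head, assertion, provenance and publication-info graphs encoding one
#' gene-disease association (implicit flavor, carrying a percentile rank)
#' or one literature co-occurrence (explicit flavor, carrying a document
#' id).  Triples are stored as 3-column character matrices whose cells are
#' already in N-Triples term syntax.
#'
#' @slot uri the nanopublication URI.
#' @slot head,assertion,provenance,pubinfo character matrices, columns
#'   subject / predicate / object.
#' @export
setClass("Nanopub",
  representation(uri = "character", head = "matrix", assertion = "matrix",
                 provenance = "matrix", pubinfo = "matrix"))

setValidity("Nanopub", function(object) {
  for (g in list(object@head, object@assertion, object@provenance,
                 object@pubinfo)) {
    if (!is.character(g) || ncol(g) != 3L)
      return("each graph must be a 3-column character matrix")
  }
  if (nrow(object@head) < 4L)
    return("head graph must type the nanopub and link its three parts")
  TRUE
})

setMethod("show", "Nanopub", function(object) {
  cat("Nanopub <", object@uri, ">\n", sep = "")
  cat("  head:", nrow(object@head), " assertion:", nrow(object@assertion),
      " provenance:", nrow(object@provenance), " pubinfo:",
      nrow(object@pubinfo), " (", tripleCount(object), "triples )\n")
})

#' @export
setMethod("npGraphs", "Nanopub", function(x)
  list(head = x@head, assertion = x@assertion,
       provenance = x@provenance, pubinfo = x@pubinfo))

#' Total triples across the four named graphs
#' @param x a \linkS4class{Nanopub}.
#' @export
setMethod("tripleCount", "Nanopub", function(x)
  nrow(x@head) + nrow(x@assertion) + nrow(x@provenance) + nrow(x@pubinfo))

## ---------------------------------------------------------------------------
## SynthSpec
## ---------------------------------------------------------------------------

#' Specification of a synthetic literature corpus
#'
#' Describes a corpus with planted Swanson A-B-C structure: for every
#' planted bridge (gene g, bridge concept y, disease d) one disjoint set of
#' documents mentions \{g, y\} and another mentions \{y, d\}; g and d never
#' co-occur unless the pair is planted as explicit.  Background concepts
#' follow a Zipf abundance law and supply optional noise mentions.
#'
#' @slot nGenes,nDiseases,nBridgeConcepts,nBackgroundConcepts counts.
#' @slot docsPerLink documents per planted link.
#' @slot zipfExponent abundance skew (>= 0) of background concepts.
#' @slot noiseRate per-document probability of one extra background
#'   mention, in \[0, 1).
#' @slot plantedBridges data.frame (gene, bridge, disease).
#' @slot plantedExplicit data.frame (gene, disease).
#' @slot nHomonymPairs background concept pairs given a shared synonym.
#' @slot seed RNG seed; the corpus is a pure function of the spec.
#' @export
setClass("SynthSpec",
  representation(nGenes = "numeric", nDiseases = "numeric",
                 nBridgeConcepts = "numeric",
                 nBackgroundConcepts = "numeric", docsPerLink = "numeric",
                 zipfExponent = "numeric", noiseRate = "numeric",
                 plantedBridges = "data.frame",
                 plantedExplicit = "data.frame",
                 nHomonymPairs = "numeric", seed = "numeric"))

setValidity("SynthSpec", function(object) {
  cnt <- c(object@nGenes, object@nDiseases, object@nBridgeConcepts,
           object@nBackgroundConcepts, object@docsPerLink,
           object@nHomonymPairs)
  if (any(cnt < 0)) return("counts must be nonnegative")
  if (object@noiseRate < 0 || object@noiseRate >= 1)
    return("noiseRate must be in [0, 1)")
  if (object@zipfExponent < 0) return("zipfExponent must be >= 0")
  if (nrow(object@plantedBridges) &&
      !all(c("gene", "bridge", "disease") %in%
           colnames(object@plantedBridges)))
    return("plantedBridges needs columns gene, bridge, disease")
  if (nrow(object@plantedExplicit) &&
      !all(c("gene", "disease") %in% colnames(object@plantedExplicit)))
    return("plantedExplicit needs columns gene, disease")
  ## a pair cannot be both bridged and explicit with no documents to
  ## realize the co-occurrence
  if (nrow(object@plantedBridges) && nrow(object@plantedExplicit)) {
    bp <- paste(object@plantedBridges$gene, object@plantedBridges$disease)
    ep <- paste(object@plantedExplicit$gene, object@plantedExplicit$disease)
    if (length(intersect(bp, ep)) && object@docsPerLink == 0)
      return("a pair is both bridged and explicit with docsPerLink = 0")
  }
  TRUE
})

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec:", object@nGenes, "genes x", object@nDiseases,
      "diseases;", nrow(object@plantedBridges), "bridges,",
      nrow(object@plantedExplicit), "explicit pairs;",
      object@nBackgroundConcepts, "background concepts (Zipf s =",
      object@zipfExponent, "); noise =", object@noiseRate,
      "; seed =", object@seed, "\n")
})
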