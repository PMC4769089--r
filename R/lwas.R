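## Full gene x disease LWAS and corpus-level statistics.

#' Run a literature-wide association study
#'
#' Builds concept profiles for every gene and disease at or above the
#' document-frequency cutoff, scores every gene-disease pair with both
#' profiles by sparse inner product, classifies pairs as explicit or
#' implicit from the index, and percentile-ranks the scores.
#'
#' Percentiles use the strictly-below convention against either the full
#' ensemble of scored pairs (\code{percentileMode = "full"}) or a seeded
#' random reference sample (\code{"sampled"}, size
#' \code{referenceSize}), mirroring projection onto a fixed random set of
#' gene-disease association scores.
#'
#' @param index a \linkS4class{ConceptIndex}.
#' @param thesaurus a \linkS4class{ConceptThesaurus} containing at least
#'   one gene and one disease concept.
#' @param minDocs profile cutoff (default 5 abstracts).
#' @param percentileMode "full" or "sampled".
#' @param referenceSize reference sample size for sampled mode (default
#'   1500).
#' @param seed RNG seed for the reference sample; recorded in the config.
#' @param until optional corpus cutoff date recorded in the config (apply
#'   it at \code{\link{buildConceptIndex}} time).
#' @return an \linkS4class{LwasRun}.
#' @export
runLwas <- function(index, thesaurus, minDocs = 5,
                    percentileMode = c("full", "sampled"),
                    referenceSize = 1500, seed = NULL, until = NULL) {
  percentileMode <- match.arg(percentileMode)
  types <- semanticTypes(thesaurus)
  genes <- names(types)[types == "gene"]
  diseases <- names(types)[types == "disease"]
  if (!length(genes) || !length(diseases))
    stop("thesaurus must contain both gene and disease concepts")

  profiles <- buildProfiles(index, c(genes, diseases), minDocs = minDocs)
  g_ok <- sort(intersect(genes, names(profiles)))
  d_ok <- sort(intersect(diseases, names(profiles)))

  res <- .score_pairs(index, profiles, g_ok, d_ok)

  ref <- switch(percentileMode,
    full = res$score,
    sampled = {
      if (!is.null(seed)) set.seed(seed)
      res$score[sample.int(nrow(res), min(referenceSize, nrow(res)))]
    })
  res$percentile <- if (nrow(res)) percentileRank(res$score, ref) else
    numeric()

  LwasRun(nGenes = length(genes), nDiseases = length(diseases),
          pairsScored = length(g_ok) * length(d_ok),
          nExplicit = sum(res$explicit), results = res,
          profiles = profiles, index = index, thesaurus = thesaurus,
          config = list(min_docs = minDocs,
                        percentile_mode = percentileMode,
                        reference_size = if (percentileMode == "sampled")
                          referenceSize else length(ref),
                        seed = seed, until = until,
                        n_docs = nDocs(index)))
}

## score all gene x disease profile pairs through sparse matrix products
.score_pairs <- function(index, profiles, genes, diseases) {
  if (!length(genes) || !length(diseases))
    return(data.frame(gene_id = character(), disease_id = character(),
                      score = numeric(), n_overlap = numeric(),
                      explicit = logical(), n_cooccurrences = numeric(),
                      stringsAsFactors = FALSE))
  cids <- rownames(index@incidence)
  tomat <- function(seeds) {
    ws <- lapply(seeds, function(s) profiles[[s]]@weights)
    Matrix::sparseMatrix(
      i = match(unlist(lapply(ws, names)), cids),
      j = rep.int(seq_along(seeds), lengths(ws)),
      x = unlist(ws, use.names = FALSE),
      dims = c(length(cids), length(seeds)),
      dimnames = list(cids, seeds))
  }
  Wg <- tomat(genes)
  Wd <- tomat(diseases)
  S <- as.matrix(Matrix::crossprod(Wg, Wd))                # scores
  Bg <- Wg; Bg@x <- rep(1, length(Bg@x))                   # 0/1 patterns
  Bd <- Wd; Bd@x <- rep(1, length(Bd@x))
  OV <- as.matrix(Matrix::crossprod(Bg, Bd))               # overlap sizes
  CO <- as.matrix(index@incidence[genes, , drop = FALSE] %*%
                    Matrix::t(index@incidence[diseases, , drop = FALSE]))
  data.frame(
    gene_id = rep(genes, times = length(diseases)),
    disease_id = rep(diseases, each = length(genes)),
    score = as.vector(S), n_overlap = as.vector(OV),
    explicit = as.vector(CO) >= 1, n_cooccurrences = as.vector(CO),
    stringsAsFactors = FALSE)
}

#' Explicit fraction of a completed run
#'
#' @param run an \linkS4class{LwasRun}.
#' @return named numeric: \code{n_explicit} and \code{fraction_pct}
#'   (percentage of scored pairs with at least one co-occurrence).
#' @export
explicitFraction <- function(run) {
  n <- run@nExplicit
  if (is.na(n)) n <- sum(run@results$explicit)
  c(n_explicit = n,
    fraction_pct = if (run@pairsScored > 0) 100 * n / run@pairsScored
    else 0)
}

#' Publication-abundance distribution of a semantic type
#'
#' @param index a \linkS4class{ConceptIndex}.
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param semanticType "gene", "disease" or "other".
#' @return data.frame (concept_id, doc_count), descending by count, ties
#'   by concept id.
#' @export
abundanceDistribution <- function(index, thesaurus, semanticType) {
  types <- semanticTypes(thesaurus)
  ids <- names(types)[types == semanticType]
  cnt <- docFrequency(index, ids)
  out <- data.frame(concept_id = ids, doc_count = unname(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$doc_count, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of top-ranked concepts covering a share of all mentions
#'
#' Smallest prefix of the rank-ordered abundance list whose summed counts
#' reach \code{mentionShare} of total mentions, as a fraction of the
#' number of concepts.  Quantifies literature-abundance skew: under a
#' Zipf law few concepts carry most mentions.
#'
#' @param abundance data.frame from \code{\link{abundanceDistribution}}.
#' @param mentionShare target share of mentions, in (0, 1].
#' @return fraction of concepts in (0, 1].
#' @export
coverageFraction <- function(abundance, mentionShare) {
  if (!nrow(abundance)) stop("empty abundance list")
  if (mentionShare <= 0 || mentionShare > 1)
    stop("mentionShare must be in (0, 1]")
  total <- sum(abundance$doc_count)
  if (total <= 0) stop("abundance list has no mentions")
  k <- which(cumsum(abundance$doc_count) >= mentionShare * total)[1L]
  k / nrow(abundance)
}
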