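## Profile matching: inner-product scores, connecting-concept
## contributions, explicit/implicit classification, percentile ranks.

#' Match score of two concept profiles
#'
#' Inner product of the two sparse weight vectors over their shared
#' concepts; no length normalization.  Symmetric in its arguments.
#'
#' @param pA,pB \linkS4class{ConceptProfile} objects.
#' @return list with \code{score} (nonnegative) and \code{n_overlap}
#'   (number of shared profile concepts); score is 0 iff the overlap is
#'   empty.
#' @export
#' @examples
#' # two profiles sharing one concept with weights 0.5 and 0.4
#' pA <- new("ConceptProfile", seed = "a",
#'           weights = c(y1 = 0.5, y2 = 0.2), builtFromNDocs = 10,
#'           minDocs = 5)
#' pB <- new("ConceptProfile", seed = "b",
#'           weights = c(y1 = 0.4, y3 = 0.1), builtFromNDocs = 10,
#'           minDocs = 5)
#' matchScore(pA, pB)   # score 0.2, overlap 1
matchScore <- function(pA, pB) {
  shared <- intersect(names(pA@weights), names(pB@weights))
  list(score = sum(pA@weights[shared] * pB@weights[shared]),
       n_overlap = length(shared))
}

#' Connecting-concept contributions to a match score
#'
#' Decomposes a profile match score into the percentage contributed by
#' each shared concept: share(y) = 100 * wA(y) * wB(y) / score.  Shares
#' sum to 100; rows are sorted by share descending with ties broken by
#' concept id.
#'
#' @param pA,pB \linkS4class{ConceptProfile} objects with nonzero overlap.
#' @param topN keep the strongest \code{topN} rows (default all).
#' @return data.frame with columns rank, concept_id, weight_a, weight_b,
#'   contribution_pct.
#' @export
connectingConcepts <- function(pA, pB, topN = Inf) {
  shared <- intersect(names(pA@weights), names(pB@weights))
  prod <- pA@weights[shared] * pB@weights[shared]
  score <- sum(prod)
  if (score <= 0) stop("zero match score: no connecting concepts")
  ord <- order(-prod, shared)
  shared <- shared[ord]
  prod <- prod[ord]
  out <- data.frame(rank = seq_along(shared), concept_id = shared,
                    weight_a = unname(pA@weights[shared]),
                    weight_b = unname(pB@weights[shared]),
                    contribution_pct = unname(100 * prod / score),
                    stringsAsFactors = FALSE)
  head(out, topN)
}

#' Classify a concept pair as explicit or implicit
#'
#' A pair is explicit when the two concepts co-occur in at least one
#' document; the shared documents are its evidence.
#'
#' @param index a \linkS4class{ConceptIndex}.
#' @param a,b concept ids.
#' @return list with \code{explicit} (logical) and \code{evidence_docs}
#'   (sorted doc ids, empty when implicit).
#' @export
classifyExplicit <- function(index, a, b) {
  co <- cooccurrence(index, a, b)
  list(explicit = co$contingency@n11 >= 1, evidence_docs = co$shared)
}

#' Percentile rank of a score within a reference ensemble
#'
#' Strictly-below convention: 100 * #\{reference < score\} / |reference|.
#' A score equal to every reference value therefore ranks 0.  Monotone
#' non-decreasing in the score for a fixed reference.
#'
#' @param score numeric score(s).
#' @param reference non-empty numeric vector of ensemble scores.
#' @return numeric in \[0, 100\], one per score.
#' @export
percentileRank <- function(score, reference) {
  if (!length(reference)) stop("empty reference ensemble")
  sr <- sort(reference)
  ## with left.open, a score equal to a reference value falls in the lower
  ## interval, so findInterval counts the references strictly below it
  below <- findInterval(score, sr, left.open = TRUE)
  100 * below / length(sr)
}

#' Ranked candidate list for a fixed concept
#'
#' All scored partners of the opposite semantic type, sorted by match
#' score descending (ties by concept id), each carrying its explicit
#' flag, evidence documents and strongest connecting concept.
#'
#' @param run an \linkS4class{LwasRun} produced by \code{\link{runLwas}}.
#' @param fixedConcept gene or disease concept id.
#' @param topN number of rows to return (default 10).
#' @return data.frame with columns rank, concept_id, label, score,
#'   percentile, explicit, n_cooccurrences, evidence_doc_ids
#'   (pipe-separated), top_connecting_concept.
#' @export
rankCandidates <- function(run, fixedConcept, topN = 10) {
  res <- run@results
  th <- run@thesaurus
  if (is.null(th) || is.null(run@index))
    stop("rankCandidates needs a run carrying its index and thesaurus")
  types <- semanticTypes(th)
  if (!fixedConcept %in% names(types))
    stop("unknown concept: ", fixedConcept)
  side <- types[[fixedConcept]]
  if (side == "gene") {
    rows <- res[res$gene_id == fixedConcept, , drop = FALSE]
    rows$concept_id <- rows$disease_id
  } else if (side == "disease") {
    rows <- res[res$disease_id == fixedConcept, , drop = FALSE]
    rows$concept_id <- rows$gene_id
  } else stop("fixed concept must be a gene or a disease")
  if (!nrow(rows))
    return(data.frame(rank = integer(), concept_id = character(),
                      label = character(), score = numeric(),
                      percentile = numeric(), explicit = logical(),
                      n_cooccurrences = numeric(),
                      evidence_doc_ids = character(),
                      top_connecting_concept = character(),
                      stringsAsFactors = FALSE))
  rows <- rows[order(-rows$score, rows$concept_id), , drop = FALSE]
  rows <- head(rows, topN)
  lab <- th@concepts$preferred_name[match(rows$concept_id,
                                          th@concepts$concept_id)]
  fixed_prof <- run@profiles[[fixedConcept]]
  ev <- character(nrow(rows))
  topc <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    if (rows$explicit[i]) {
      ev[i] <- paste(cooccurrence(run@index, fixedConcept,
                                  rows$concept_id[i])$shared,
                     collapse = "|")
    }
    other <- run@profiles[[rows$concept_id[i]]]
    if (!is.null(fixed_prof) && !is.null(other) && rows$score[i] > 0)
      topc[i] <- connectingConcepts(fixed_prof, other,
                                    topN = 1)$concept_id
  }
  data.frame(rank = seq_len(nrow(rows)), concept_id = rows$concept_id,
             label = lab, score = rows$score, percentile = rows$percentile,
             explicit = rows$explicit,
             n_cooccurrences = rows$n_cooccurrences,
             evidence_doc_ids = ev, top_connecting_concept = topc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a ranked candidate list as TSV
#' @param ranked data.frame from \code{\link{rankCandidates}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRankedList <- function(ranked, path) {
  out <- ranked
  out$explicit <- as.integer(out$explicit)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
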