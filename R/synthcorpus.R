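## Synthetic corpora with planted Swanson A-B-C structure.
##
## For every planted bridge (gene g, bridge concept y, disease d) one set
## of documents mentions {g, y} and a disjoint set mentions {y, d}; g and
## d never share a document unless the pair is planted as explicit.
## Background concepts follow a Zipf abundance law and supply the noise
## mentions, so noise can never create an unplanted gene-disease
## co-occurrence.  Documents are bags of concept surface forms joined
## into pseudo-sentences: the contingency model only sees per-document
## presence, so no natural-language realism is attempted.

#' Construct a synthetic corpus specification
#'
#' Defaults describe the reference validation scenario: 12 genes x 8
#' diseases, 10 planted bridges (genes 1-10 each linked to a disease
#' through a dedicated bridge concept), 2 planted explicit pairs on the
#' remaining genes, 100 Zipf-distributed background concepts
#' (exponent 1.1), 5 documents per planted link (the profile cutoff), a
#' 5% noise rate and one homonymous synonym pair.
#'
#' @param nGenes,nDiseases,nBridgeConcepts,nBackgroundConcepts counts.
#' @param docsPerLink documents per planted link (default 5).
#' @param zipfExponent background abundance skew (default 1.1).
#' @param noiseRate per-document probability of one extra background
#'   mention (default 0.05).
#' @param plantedBridges data.frame (gene, bridge, disease) of concept
#'   ids; NULL plants one bridge per bridge concept, cycling genes and
#'   diseases.
#' @param plantedExplicit data.frame (gene, disease); NULL plants 2
#'   explicit pairs on the first genes left unbridged (none if all genes
#'   are bridged).
#' @param nHomonymPairs background concept pairs given a shared synonym
#'   (the synonym is never emitted into documents, so co-occurrence
#'   guarantees are unaffected).
#' @param seed RNG seed (default 42); the corpus is a pure function of
#'   the spec.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nGenes = 12, nDiseases = 8, nBridgeConcepts = 10,
                      nBackgroundConcepts = 100, docsPerLink = 5,
                      zipfExponent = 1.1, noiseRate = 0.05,
                      plantedBridges = NULL, plantedExplicit = NULL,
                      nHomonymPairs = 1, seed = 42) {
  gid <- function(i) sprintf("G%02d", i)
  did <- function(i) sprintf("D%02d", i)
  yid <- function(i) sprintf("Y%02d", i)
  if (is.null(plantedBridges)) {
    if (nBridgeConcepts > 0 && nGenes > 0 && nDiseases > 0) {
      i <- seq_len(nBridgeConcepts)
      plantedBridges <- data.frame(
        gene = gid((i - 1L) %% nGenes + 1L), bridge = yid(i),
        disease = did((i - 1L) %% nDiseases + 1L),
        stringsAsFactors = FALSE)
    } else {
      plantedBridges <- data.frame(gene = character(),
                                   bridge = character(),
                                   disease = character(),
                                   stringsAsFactors = FALSE)
    }
  }
  if (is.null(plantedExplicit)) {
    free <- setdiff(gid(seq_len(nGenes)), plantedBridges$gene)
    free <- head(free, 2L)
    plantedExplicit <- if (length(free) && nDiseases > 0) {
      data.frame(gene = free,
                 disease = did(seq_along(free) %% max(nDiseases, 1L) + 1L),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = character(), disease = character(),
                 stringsAsFactors = FALSE)
    }
  }
  new("SynthSpec", nGenes = nGenes, nDiseases = nDiseases,
      nBridgeConcepts = nBridgeConcepts,
      nBackgroundConcepts = nBackgroundConcepts,
      docsPerLink = docsPerLink, zipfExponent = zipfExponent,
      noiseRate = noiseRate, plantedBridges = plantedBridges,
      plantedExplicit = plantedExplicit,
      nHomonymPairs = nHomonymPairs, seed = seed)
}

#' Miniature disease-gene demo specification
#'
#' A small Seckel-syndrome-like scenario used in the documentation: one
#' disease, one causative gene with explicit literature links, three
#' further genes connected to the disease only through a shared
#' microcephaly-like bridge concept, and a noisy Zipf background.
#'
#' @return a \linkS4class{SynthSpec}.
#' @export
demoSynthSpec <- function() {
  synthSpec(
    nGenes = 4, nDiseases = 1, nBridgeConcepts = 1,
    nBackgroundConcepts = 40, docsPerLink = 5, zipfExponent = 1.1,
    noiseRate = 0.05,
    plantedBridges = data.frame(gene = c("G02", "G03", "G04"),
                                bridge = "Y01", disease = "D01",
                                stringsAsFactors = FALSE),
    plantedExplicit = data.frame(gene = "G01", disease = "D01",
                                 stringsAsFactors = FALSE),
    nHomonymPairs = 1, seed = 42)
}

.synth_thesaurus_rows <- function(spec) {
  gid <- sprintf("G%02d", seq_len(spec@nGenes))
  did <- sprintf("D%02d", seq_len(spec@nDiseases))
  yid <- sprintf("Y%02d", seq_len(spec@nBridgeConcepts))
  bid <- sprintf("B%03d", seq_len(spec@nBackgroundConcepts))
  block <- function(ids, type, terms, xrefs) {
    data.frame(concept_id = ids, semantic_type = rep(type, length(ids)),
               term = terms, is_preferred = rep(1L, length(ids)),
               xrefs = xrefs, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    block(gid, "gene", sprintf("gene%03d", seq_along(gid)),
          sprintf("EG:%d", 1000L + seq_along(gid))),
    block(did, "disease", sprintf("dis%03d", seq_along(did)),
          sprintf("OMIM:%d", 200000L + seq_along(did))),
    block(yid, "other", sprintf("brdg%03d", seq_along(yid)),
          sprintf("UMLS:C%06d", 10000L + seq_along(yid))),
    block(bid, "other", sprintf("bkg%03d", seq_along(bid)),
          sprintf("UMLS:C%06d", 20000L + seq_along(bid))))
  ## homonymous synonyms shared by background concept pairs (never
  ## emitted into documents)
  nh <- min(spec@nHomonymPairs, floor(spec@nBackgroundConcepts / 2))
  if (nh > 0) {
    j <- seq_len(nh)
    rows <- rbind(rows,
      data.frame(concept_id = bid[2L * j - 1L], semantic_type = "other",
                 term = sprintf("homon%03d", j), is_preferred = 0L,
                 xrefs = "", stringsAsFactors = FALSE),
      data.frame(concept_id = bid[2L * j], semantic_type = "other",
                 term = sprintf("homon%03d", j), is_preferred = 0L,
                 xrefs = "", stringsAsFactors = FALSE))
  }
  rows
}

#' Generate a synthetic corpus, thesaurus and ground truth
#'
#' Fully reproducible from the spec's seed: the same spec yields
#' byte-identical corpora.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with elements \code{corpus} (data.frame for
#'   \code{\link{buildConceptIndex}}), \code{thesaurus}
#'   (\linkS4class{ConceptThesaurus}), and \code{truth}: a list with
#'   \code{tags} (doc_id, concept_id), \code{bridges}, \code{explicit},
#'   and \code{abundance} (realized background mention counts).
#' @export
generateCorpus <- function(spec) {
  methods::validObject(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec@seed)

  rows <- .synth_thesaurus_rows(spec)
  th <- conceptThesaurus(rows)
  surface <- structure(rows$term[rows$is_preferred == 1L],
                       names = rows$concept_id[rows$is_preferred == 1L])
  bid <- sprintf("B%03d", seq_len(spec@nBackgroundConcepts))

  docs <- list()
  add_doc <- function(concepts) docs[[length(docs) + 1L]] <<- concepts

  br <- spec@plantedBridges
  for (k in seq_len(nrow(br))) {
    for (r in seq_len(spec@docsPerLink))
      add_doc(c(br$gene[k], br$bridge[k]))
    for (r in seq_len(spec@docsPerLink))
      add_doc(c(br$bridge[k], br$disease[k]))
  }
  ex <- spec@plantedExplicit
  for (k in seq_len(nrow(ex))) {
    for (r in seq_len(spec@docsPerLink))
      add_doc(c(ex$gene[k], ex$disease[k]))
  }
  n_structured <- length(docs)

  ## Zipf-abundant background documents
  if (spec@nBackgroundConcepts >= 2) {
    zw <- seq_len(spec@nBackgroundConcepts)^(-spec@zipfExponent)
    zw <- zw / sum(zw)
    n_bg_docs <- 2L * spec@nBackgroundConcepts
    for (k in seq_len(n_bg_docs))
      add_doc(sample(bid, size = min(2L, spec@nBackgroundConcepts),
                     replace = FALSE, prob = zw))
  } else zw <- rep(1, spec@nBackgroundConcepts)

  ## noise: one extra background mention per document with prob noiseRate
  if (spec@noiseRate > 0 && spec@nBackgroundConcepts > 0) {
    for (k in seq_along(docs)) {
      if (runif(1) < spec@noiseRate) {
        extra <- sample(bid, 1L, prob = zw)
        docs[[k]] <- union(docs[[k]], extra)
      }
    }
  }

  n <- length(docs)
  doc_ids <- sprintf("PM%06d", seq_len(n))
  dates <- as.Date("2000-01-01") +
    sample.int(as.integer(as.Date("2014-12-31") - as.Date("2000-01-01")),
               n, replace = TRUE)

  title <- character(n)
  abstract <- character(n)
  keywords <- vector("list", n)
  for (k in seq_len(n)) {
    forms <- unname(surface[docs[[k]]])
    title[k] <- paste("A study of", forms[1L])
    if (k %% 3L == 0L && length(forms) > 1L) {
      keywords[[k]] <- forms[length(forms)]
      forms <- forms[-length(forms)]
    } else keywords[[k]] <- character()
    abstract[k] <- paste("We report on", paste(forms, collapse = " and "),
                         "in this corpus.")
  }
  corpus <- data.frame(doc_id = doc_ids, title = title,
                       abstract = abstract, keywords = I(keywords),
                       date = as.character(dates),
                       stringsAsFactors = FALSE)

  tags <- data.frame(
    doc_id = rep(doc_ids, lengths(docs)),
    concept_id = unlist(docs, use.names = FALSE),
    stringsAsFactors = FALSE)
  abund_tab <- table(factor(tags$concept_id[tags$concept_id %in% bid],
                            levels = bid))
  truth <- list(tags = tags[order(tags$doc_id, tags$concept_id), ],
                bridges = br, explicit = ex,
                abundance = data.frame(concept_id = bid,
                                       doc_count = as.numeric(abund_tab),
                                       stringsAsFactors = FALSE),
                n_structured_docs = n_structured)
  rownames(truth$tags) <- NULL
  list(corpus = corpus, thesaurus = th, truth = truth)
}

#' Evaluate recovery of planted bridged pairs from an LWAS run
#'
#' For every planted bridge (g, y, d): the rank of d among all scored
#' diseases for g (score descending, ties by concept id), the pair's
#' percentile, explicit flag and score.  The summary fraction counts
#' bridged pairs whose percentile exceeds the median percentile of the
#' unbridged pairs (scored pairs that are neither planted bridges nor
#' planted explicit pairs).
#'
#' @param truth ground-truth list from \code{\link{generateCorpus}}.
#' @param run an \linkS4class{LwasRun} on the generated corpus.
#' @return list with \code{report} (one row per planted bridge) and
#'   \code{summary} (recovery_fraction, median_unbridged_percentile,
#'   n_bridged, n_unbridged).
#' @export
evaluateRecovery <- function(truth, run) {
  res <- run@results
  br <- truth$bridges
  if (!nrow(br))
    return(list(report = data.frame(), summary = list(
      recovery_fraction = NA_real_, median_unbridged_percentile = NA_real_,
      n_bridged = 0L, n_unbridged = nrow(res))))
  key <- paste(res$gene_id, res$disease_id)
  bkey <- unique(paste(br$gene, br$disease))
  ekey <- paste(truth$explicit$gene, truth$explicit$disease)
  is_bridged <- key %in% bkey
  is_unbridged <- !is_bridged & !key %in% ekey
  med_unbr <- if (any(is_unbridged))
    median(res$percentile[is_unbridged]) else NA_real_

  report <- do.call(rbind, lapply(seq_len(nrow(br)), function(k) {
    g <- br$gene[k]; d <- br$disease[k]
    mine <- res[res$gene_id == g, , drop = FALSE]
    mine <- mine[order(-mine$score, mine$disease_id), , drop = FALSE]
    pos <- match(d, mine$disease_id)
    row <- res[res$gene_id == g & res$disease_id == d, , drop = FALSE]
    data.frame(gene = g, bridge = br$bridge[k], disease = d,
               rank = if (is.na(pos)) NA_integer_ else pos,
               n_candidates = nrow(mine),
               score = if (nrow(row)) row$score else NA_real_,
               percentile = if (nrow(row)) row$percentile else NA_real_,
               explicit = if (nrow(row)) row$explicit else NA,
               stringsAsFactors = FALSE)
  }))
  scored <- !is.na(report$percentile)
  frac <- if (any(scored) && !is.na(med_unbr))
    mean(report$percentile[scored] > med_unbr) else NA_real_
  list(report = report,
       summary = list(recovery_fraction = frac,
                      median_unbridged_percentile = med_unbr,
                      n_bridged = nrow(report),
                      n_unbridged = sum(is_unbridged)))
}
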