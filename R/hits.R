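## External (GWAS-catalogue-like) hit tables: filtering cascade,
## significance classes, fold enrichment against LWAS percentiles.

#' Read a hit table TSV
#'
#' Columns gene_text, trait_text, p_value, study_id, pub_date.
#'
#' @param path TSV file.
#' @return data.frame of hit records.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = c(
                             "gene_text", "trait_text", "study_id",
                             "pub_date")))
  tab$p_value <- as.numeric(tab$p_value)
  tab
}

#' Map free text unambiguously to one concept of a given type
#'
#' The normalized text must resolve through the thesaurus term map to
#' exactly one concept of the required semantic type.  When several
#' candidates exist, a unique case-sensitive match between the raw text
#' and a candidate's raw term is preferred; otherwise the mapping fails.
#'
#' @param text gene symbol or trait description.
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param type required semantic type ("gene" or "disease").
#' @return concept id, or NA when not unambiguously mappable.
#' @export
mapTextToConcept <- function(text, thesaurus, type) {
  cand <- termLookup(thesaurus, text)
  if (!length(cand)) return(NA_character_)
  types <- semanticTypes(thesaurus)
  cand <- cand[types[cand] == type]
  if (length(cand) == 1L) return(cand)
  if (length(cand) > 1L) {
    cs <- vapply(cand, function(id) {
      any(thesaurus@terms$term[thesaurus@terms$concept_id == id] == text)
    }, logical(1))
    if (sum(cs) == 1L) return(cand[cs])
  }
  NA_character_
}

#' Filter an external hit table down to scorable implicit pairs
#'
#' Applies, in order: (1) drop records whose (gene_text, trait_text) pair
#' is already in \code{priorHits}; (2) drop trait descriptions containing
#' "response (to)" or "response to" (case-insensitive); (3) drop records
#' not unambiguously mappable to exactly one gene and one disease concept
#' (\code{\link{mapTextToConcept}}); (4) drop pairs with an explicit
#' co-occurrence in the corpus; (5) drop pairs lacking a concept profile
#' on either side; (6) deduplicate pairs keeping the smallest p-value.
#' Every step's removals are logged so the cascade is auditable.
#'
#' @param records data.frame of hit records (see
#'   \code{\link{readHitTable}}).
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param index a \linkS4class{ConceptIndex}.
#' @param priorHits optional data.frame with columns gene_text,
#'   trait_text of previously reported hits.
#' @param minDocs profile cutoff used for step 5 (default 5).
#' @return list with \code{pairs} (gene_id, disease_id, gene_text,
#'   trait_text, p_value, study_id) and \code{ledger} (step, description,
#'   n_removed).
#' @export
filterHits <- function(records, thesaurus, index, priorHits = NULL,
                       minDocs = 5) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  ledger <- data.frame(step = integer(), description = character(),
                       n_removed = integer(), stringsAsFactors = FALSE)
  log_step <- function(step, desc, before, after) {
    ledger <<- rbind(ledger, data.frame(step = step, description = desc,
                                        n_removed = before - after,
                                        stringsAsFactors = FALSE))
  }

  n0 <- nrow(rec)
  if (!is.null(priorHits) && nrow(priorHits)) {
    key <- paste(rec$gene_text, rec$trait_text, sep = "\r")
    prior <- paste(priorHits$gene_text, priorHits$trait_text, sep = "\r")
    rec <- rec[!key %in% prior, , drop = FALSE]
  }
  log_step(1L, "already reported in prior studies", n0, nrow(rec))

  n0 <- nrow(rec)
  resp <- grepl("response (to)", rec$trait_text, fixed = TRUE) |
    grepl("response to", rec$trait_text, ignore.case = TRUE) |
    grepl("response \\(to\\)", rec$trait_text, ignore.case = TRUE)
  rec <- rec[!resp, , drop = FALSE]
  log_step(2L, "trait mentions 'response (to)'", n0, nrow(rec))

  n0 <- nrow(rec)
  rec$gene_id <- vapply(rec$gene_text, mapTextToConcept, character(1),
                        thesaurus = thesaurus, type = "gene",
                        USE.NAMES = FALSE)
  rec$disease_id <- vapply(rec$trait_text, mapTextToConcept, character(1),
                           thesaurus = thesaurus, type = "disease",
                           USE.NAMES = FALSE)
  rec <- rec[!is.na(rec$gene_id) & !is.na(rec$disease_id), , drop = FALSE]
  log_step(3L, "not unambiguously mappable to gene+disease concepts",
           n0, nrow(rec))

  n0 <- nrow(rec)
  if (nrow(rec)) {
    expl <- mapply(function(g, d) classifyExplicit(index, g, d)$explicit,
                   rec$gene_id, rec$disease_id)
    rec <- rec[!expl, , drop = FALSE]
  }
  log_step(4L, "explicit co-occurrence in the corpus", n0, nrow(rec))

  n0 <- nrow(rec)
  if (nrow(rec)) {
    dfg <- docFrequency(index, rec$gene_id)
    dfd <- docFrequency(index, rec$disease_id)
    rec <- rec[dfg >= minDocs & dfd >= minDocs, , drop = FALSE]
  }
  log_step(5L, "no concept profile on one or both sides", n0, nrow(rec))

  n0 <- nrow(rec)
  if (nrow(rec)) {
    key <- paste(rec$gene_id, rec$disease_id, sep = "\r")
    rec <- rec[order(key, rec$p_value), , drop = FALSE]
    rec <- rec[!duplicated(paste(rec$gene_id, rec$disease_id, sep = "\r")),
               , drop = FALSE]
  }
  log_step(6L, "duplicate pair (kept smallest p-value)", n0, nrow(rec))

  keep <- intersect(c("gene_id", "disease_id", "gene_text", "trait_text",
                      "p_value", "study_id"), colnames(rec))
  rownames(rec) <- NULL
  list(pairs = rec[keep], ledger = ledger)
}

#' Significance class of a GWAS p-value
#'
#' "high" below 1e-8, "intermediate" in \[1e-8, 1e-5), "below" otherwise.
#'
#' @param p p-value(s) in (0, 1].
#' @return character vector of classes.
#' @export
classifySignificance <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  ifelse(p < 1e-8, "high", ifelse(p < 1e-5, "intermediate", "below"))
}

#' Fold enrichment of hits above a percentile cutoff
#'
#' k_pass hits at or above the cutoff out of n give pass% = 100*k/n; the
#' fold enrichment is pass% divided by the random expectation
#' (100 - cutoff)%.
#'
#' @param percentiles LWAS percentile ranks of the hit pairs (non-empty).
#' @param cutoffPct percentile cutoff in (0, 100).
#' @return named numeric: k_pass, n, pass_pct, fold.
#' @export
#' @examples
#' # 45 of 194 pairs above the 95th percentile: ~23%, ~4.6-fold
#' enrichment(c(rep(99, 45), rep(50, 149)), 95)
enrichment <- function(percentiles, cutoffPct) {
  if (!length(percentiles)) stop("empty percentile list")
  if (cutoffPct <= 0 || cutoffPct >= 100)
    stop("cutoff must be in (0, 100)")
  k <- sum(percentiles >= cutoffPct)
  n <- length(percentiles)
  pass <- 100 * k / n
  c(k_pass = k, n = n, pass_pct = pass, fold = pass / (100 - cutoffPct))
}
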