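## Thesaurus IO and homonym statistics.
##
## TSV dialect: header row with columns concept_id, semantic_type, term,
## is_preferred, xrefs (pipe-separated, may be empty); UTF-8, tab-separated.
## One row per (concept, synonym); the preferred row names the concept.

#' Build a thesaurus from a long-format synonym table
#'
#' @param rows data.frame with columns concept_id, semantic_type, term,
#'   is_preferred (0/1), xrefs (pipe-separated, may be empty strings or NA).
#' @param stopwords,stemmer normalization configuration, recorded in the
#'   object so documents are normalized identically at indexing time.
#' @return a \linkS4class{ConceptThesaurus}.
#' @export
conceptThesaurus <- function(rows, stopwords = defaultStopwords(),
                             stemmer = c("suffix", "identity")) {
  stemmer <- match.arg(stemmer)
  need <- c("concept_id", "semantic_type", "term", "is_preferred", "xrefs")
  miss <- setdiff(need, colnames(rows))
  if (length(miss))
    stop("thesaurus table is missing column(s): ",
         paste(miss, collapse = ", "))
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  rows$xrefs[is.na(rows$xrefs)] <- ""
  bad <- !rows$semantic_type %in% c("gene", "disease", "other")
  if (any(bad))
    stop("unknown semantic_type '", rows$semantic_type[which(bad)[1L]],
         "' in row ", which(bad)[1L])

  ## collapse duplicate (concept_id, term) rows
  rows <- rows[!duplicated(rows[c("concept_id", "term")]), , drop = FALSE]

  if (nrow(rows)) {
    rows$norm <- vapply(rows$term, .norm_key, character(1),
                        stopwords = stopwords, stemmer = stemmer,
                        USE.NAMES = FALSE)
    rows <- rows[nzchar(rows$norm), , drop = FALSE]
  } else {
    rows$norm <- character(0)
  }

  concepts <- .concept_table(rows)
  terms <- rows[order(rows$concept_id, -as.integer(rows$is_preferred),
                      rows$term),
                c("concept_id", "term", "is_preferred", "norm"),
                drop = FALSE]
  rownames(terms) <- NULL

  term_map <- lapply(split(terms$concept_id, terms$norm),
                     function(ids) sort(unique(ids)))

  new("ConceptThesaurus", concepts = concepts, terms = terms,
      termMap = term_map, stopwords = as.character(stopwords),
      stemmer = stemmer)
}

.concept_table <- function(rows) {
  if (!nrow(rows))
    return(data.frame(concept_id = character(), preferred_name = character(),
                      semantic_type = character(), xrefs = character(),
                      stringsAsFactors = FALSE))
  sp <- split(rows, rows$concept_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    pref <- d$term[d$is_preferred == 1]
    if (!length(pref)) pref <- d$term[1L]
    xr <- unique(unlist(strsplit(d$xrefs[nzchar(d$xrefs)], "|",
                                 fixed = TRUE)))
    data.frame(concept_id = d$concept_id[1L], preferred_name = pref[1L],
               semantic_type = d$semantic_type[1L],
               xrefs = paste(xr, collapse = "|"), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a thesaurus TSV
#'
#' @param path TSV file with header concept_id, semantic_type, term,
#'   is_preferred, xrefs.
#' @param stopwords,stemmer see \code{\link{conceptThesaurus}}.
#' @return a \linkS4class{ConceptThesaurus}.
#' @export
readThesaurus <- function(path, stopwords = defaultStopwords(),
                          stemmer = c("suffix", "identity")) {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            data.table = FALSE, encoding = "UTF-8")
  if (nrow(rows) == 0 && ncol(rows) == 0) {
    rows <- data.frame(concept_id = character(),
                       semantic_type = character(), term = character(),
                       is_preferred = character(), xrefs = character(),
                       stringsAsFactors = FALSE)
  }
  if ("is_preferred" %in% colnames(rows))
    rows$is_preferred <- as.integer(rows$is_preferred)
  conceptThesaurus(rows, stopwords = stopwords, stemmer = stemmer)
}

#' Write a thesaurus back to its TSV dialect
#'
#' Inverse of \code{\link{readThesaurus}}: a written thesaurus reloads to
#' the same concepts, terms and term map.
#'
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeThesaurus <- function(thesaurus, path) {
  t <- thesaurus@terms
  x <- thesaurus@concepts$xrefs[match(t$concept_id,
                                      thesaurus@concepts$concept_id)]
  st <- thesaurus@concepts$semantic_type[match(t$concept_id,
                                               thesaurus@concepts$concept_id)]
  out <- data.frame(concept_id = t$concept_id, semantic_type = st,
                    term = t$term, is_preferred = t$is_preferred,
                    xrefs = x, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Look up concepts by term
#'
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param term free-text term, normalized before lookup.
#' @return character vector of concept ids (possibly several: homonym;
#'   possibly empty).
#' @export
termLookup <- function(thesaurus, term) {
  key <- .norm_key(term, thesaurus@stopwords, thesaurus@stemmer)
  ids <- thesaurus@termMap[[key]]
  if (is.null(ids)) character() else ids
}

#' Counts of concepts by semantic type
#'
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @return named numeric vector with entries gene, disease, other.
#' @export
countsByType <- function(thesaurus) {
  tab <- table(factor(thesaurus@concepts$semantic_type,
                      levels = c("gene", "disease", "other")))
  c(gene = as.numeric(tab[["gene"]]), disease = as.numeric(tab[["disease"]]),
    other = as.numeric(tab[["other"]]))
}

#' Within-thesaurus homonym frequencies
#'
#' For each concept, the number of distinct other concepts sharing at
#' least one case-insensitive normalized term with it.  Symmetric by
#' construction: if a counts for b then b counts for a.
#'
#' @param x a \linkS4class{ConceptThesaurus}.
#' @param ... unused.
#' @return named integer vector over all concept ids.
#' @export
setMethod("homonymFrequencies", "ConceptThesaurus", function(x, ...) {
  ids <- x@concepts$concept_id
  out <- integer(length(ids))
  names(out) <- ids
  partners <- new.env(parent = emptyenv())
  for (members in x@termMap) {
    if (length(members) < 2L) next
    for (id in members) {
      prev <- partners[[id]]
      partners[[id]] <- union(prev, setdiff(members, id))
    }
  }
  for (id in ls(partners)) out[[id]] <- length(partners[[id]])
  out
})
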