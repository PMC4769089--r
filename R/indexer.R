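## Dictionary tagging and the concept-document index.
##
## A document is tagged by longest-match left-to-right dictionary lookup
## over the normalized token stream of title + abstract + keywords.
## Occurrence is presence-based: multiplicity within one document is
## ignored, so the index is a binary incidence matrix and every pairwise
## contingency is an exact set-intersection count.

#' Read a JSON-lines corpus
#'
#' One JSON object per line with keys \code{doc_id}, \code{title},
#' \code{abstract}, optional \code{keywords} (array) and \code{date}
#' (ISO-8601).
#'
#' @param path JSONL file.
#' @return data.frame with columns doc_id, title, abstract, keywords
#'   (list-column), date (character, NA when absent).
#' @export
readCorpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, jsonlite::fromJSON)
  data.frame(
    doc_id = vapply(docs, function(d) as.character(d$doc_id), character(1)),
    title = vapply(docs, function(d) as.character(d$title %||% ""),
                   character(1)),
    abstract = vapply(docs, function(d) as.character(d$abstract %||% ""),
                      character(1)),
    keywords = I(lapply(docs, function(d) as.character(d$keywords %||%
                                                         character()))),
    date = vapply(docs, function(d)
      if (is.null(d$date)) NA_character_ else as.character(d$date),
      character(1)),
    stringsAsFactors = FALSE)
}

#' Write a corpus as JSON-lines
#' @param corpus data.frame as returned by \code{\link{readCorpus}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(doc_id = corpus$doc_id[i], title = corpus$title[i],
                abstract = corpus$abstract[i])
    kw <- corpus$keywords[[i]]
    if (length(kw)) rec$keywords <- kw
    if (!is.na(corpus$date[i])) rec$date <- corpus$date[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read PubMed/MEDLINE-style XML into the corpus data.frame
#'
#' Minimal reader for records carrying PMID, ArticleTitle, AbstractText
#' and MeshHeading/DescriptorName elements.  Requires the xml2 package.
#'
#' @param path XML file.
#' @return corpus data.frame (see \code{\link{readCorpus}}).
#' @export
readMedlineXml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("readMedlineXml requires the xml2 package")
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation")
  if (!length(arts)) arts <- xml2::xml_find_all(doc, ".//Article")
  one <- function(a) {
    gettext1 <- function(xp) {
      n <- xml2::xml_find_first(a, xp)
      if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
    }
    kw <- xml2::xml_text(
      xml2::xml_find_all(a, ".//MeshHeading/DescriptorName"))
    data.frame(doc_id = gettext1(".//PMID"),
               title = gettext1(".//ArticleTitle"),
               abstract = paste(xml2::xml_text(
                 xml2::xml_find_all(a, ".//AbstractText")), collapse = " "),
               keywords = I(list(kw)),
               date = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(arts, one))
  out[!duplicated(out$doc_id), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## longest-match left-to-right over a token vector against a term map held
## in an environment keyed by normal-form term; returns data.frame
## (concept_id, ambiguous)
.tag_tokens <- function(tokens, map_env, max_len) {
  n <- length(tokens)
  ids <- character()
  amb <- logical()
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (L in seq.int(min(max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + L - 1L)], collapse = " ")
      hit <- map_env[[key]]
      if (!is.null(hit)) {
        ids <- c(ids, hit)
        amb <- c(amb, rep(length(hit) > 1L, length(hit)))
        matched <- L
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  if (!length(ids))
    return(data.frame(concept_id = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  ## presence-based: collapse repeats; a concept is ambiguous if any of its
  ## emitting terms was ambiguous
  df <- data.frame(concept_id = ids, ambiguous = amb,
                   stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(split(df, df$concept_id), function(d)
    data.frame(concept_id = d$concept_id[1L], ambiguous = any(d$ambiguous),
               stringsAsFactors = FALSE)))
  df <- df[order(df$concept_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.doc_tokens <- function(title, abstract, keywords, thesaurus) {
  normalizeTerm(c(title, abstract, unlist(keywords)),
                stopwords = thesaurus@stopwords,
                stemmer = thesaurus@stemmer)
}

.term_env <- function(thesaurus) {
  if (length(thesaurus@termMap))
    list2env(thesaurus@termMap, hash = TRUE, parent = emptyenv())
  else new.env(parent = emptyenv())
}

.max_term_len <- function(thesaurus) {
  if (!length(thesaurus@termMap)) return(1L)
  max(lengths(strsplit(names(thesaurus@termMap), " ", fixed = TRUE)))
}

#' Tag one document with thesaurus concepts
#'
#' Longest-match left-to-right dictionary matching over the normalized
#' token stream of title, abstract and keywords.  A term mapping to
#' several concepts (homonym) emits all of them, each flagged ambiguous.
#'
#' @param doc list or one-row data.frame with fields doc_id, title,
#'   abstract, optional keywords.
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @return data.frame with columns concept_id, ambiguous (one row per
#'   distinct concept present in the document).
#' @export
#' @examples
#' th <- conceptThesaurus(data.frame(
#'   concept_id = c("G_ATR", "D_SCKL"), semantic_type = c("gene", "disease"),
#'   term = c("ATR", "Seckel syndrome"), is_preferred = 1, xrefs = ""))
#' tagDocument(list(title = "ATR mutations cause Seckel syndrome",
#'                  abstract = ""), th)
tagDocument <- function(doc, thesaurus) {
  toks <- .doc_tokens(doc$title %||% "", doc$abstract %||% "",
                      doc$keywords %||% character(), thesaurus)
  .tag_tokens(toks, .term_env(thesaurus), .max_term_len(thesaurus))
}

#' Build the concept-document index
#'
#' Tags every document and assembles the sparse binary incidence matrix
#' (all thesaurus concepts x documents).  Deterministic given its inputs.
#'
#' @param corpus data.frame as returned by \code{\link{readCorpus}}.
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param skipAmbiguous drop tags produced by homonymous terms.
#' @param until optional ISO date; documents dated after it (or undated
#'   documents, when a cutoff is requested) are excluded, enabling
#'   retrospective time-sliced corpora.
#' @return a \linkS4class{ConceptIndex}.
#' @export
buildConceptIndex <- function(corpus, thesaurus, skipAmbiguous = FALSE,
                              until = NULL) {
  dup <- corpus$doc_id[duplicated(corpus$doc_id)]
  if (length(dup)) stop("duplicate doc_id: ", dup[1L])
  if (!is.null(until)) {
    d <- as.Date(corpus$date)
    keep <- !is.na(d) & d <= as.Date(until)
    corpus <- corpus[keep, , drop = FALSE]
  }
  env <- .term_env(thesaurus)
  maxl <- .max_term_len(thesaurus)
  n <- nrow(corpus)
  tag_i <- vector("list", n)
  amb_rows <- vector("list", n)
  for (k in seq_len(n)) {
    toks <- .doc_tokens(corpus$title[k], corpus$abstract[k],
                        corpus$keywords[[k]], thesaurus)
    tg <- .tag_tokens(toks, env, maxl)
    if (skipAmbiguous) tg <- tg[!tg$ambiguous, , drop = FALSE]
    tag_i[[k]] <- tg$concept_id
    if (any(tg$ambiguous))
      amb_rows[[k]] <- data.frame(
        doc_id = corpus$doc_id[k],
        concept_id = tg$concept_id[tg$ambiguous],
        stringsAsFactors = FALSE)
  }
  cids <- conceptIds(thesaurus)
  row_i <- match(unlist(tag_i), cids)
  col_j <- rep.int(seq_len(n), lengths(tag_i))
  inc <- Matrix::sparseMatrix(
    i = row_i, j = col_j, x = 1,
    dims = c(length(cids), n),
    dimnames = list(cids, as.character(corpus$doc_id)))
  amb <- do.call(rbind, amb_rows[!vapply(amb_rows, is.null, logical(1))])
  if (is.null(amb))
    amb <- data.frame(doc_id = character(), concept_id = character(),
                      stringsAsFactors = FALSE)
  dates <- if (n) as.Date(corpus$date) else as.Date(character())
  new("ConceptIndex", incidence = methods::as(inc, "dgCMatrix"),
      dates = dates, ambiguousTags = amb)
}

#' Documents containing a concept
#' @param index a \linkS4class{ConceptIndex}.
#' @param concept concept id.
#' @return character vector of doc ids (sorted).
#' @export
conceptDocs <- function(index, concept) {
  if (!concept %in% rownames(index@incidence)) return(character())
  sort(colnames(index@incidence)[index@incidence[concept, ] > 0])
}

#' Concepts present in a document
#' @param index a \linkS4class{ConceptIndex}.
#' @param doc doc id.
#' @return character vector of concept ids (sorted).
#' @export
docConcepts <- function(index, doc) {
  if (!doc %in% colnames(index@incidence)) return(character())
  sort(rownames(index@incidence)[index@incidence[, doc] > 0])
}

#' Document frequency of concepts
#'
#' @param x a \linkS4class{ConceptIndex}.
#' @param concept concept id(s); unindexed ids get 0.
#' @param ... unused.
#' @return named numeric vector of counts.
#' @export
setMethod("docFrequency", "ConceptIndex", function(x, concept, ...) {
  rs <- Matrix::rowSums(x@incidence)
  out <- structure(numeric(length(concept)), names = concept)
  hit <- concept %in% names(rs)
  out[hit] <- rs[concept[hit]]
  out
})

#' Pairwise co-occurrence contingency
#'
#' Exact set-intersection counts of the two concepts' document sets, plus
#' the shared doc ids (the evidence documents of an explicit association).
#' The self pair \code{a == b} yields n10 = n01 = 0.
#'
#' @param x a \linkS4class{ConceptIndex}.
#' @param a,b concept ids.
#' @param ... unused.
#' @return list with elements \code{contingency}
#'   (\linkS4class{Contingency}) and \code{shared} (sorted doc ids).
#' @export
setMethod("cooccurrence", "ConceptIndex", function(x, a, b, ...) {
  N <- ncol(x@incidence)
  da <- if (a %in% rownames(x@incidence)) x@incidence[a, ] > 0 else
    logical(N)
  db <- if (b %in% rownames(x@incidence)) x@incidence[b, ] > 0 else
    logical(N)
  n11 <- sum(da & db)
  n10 <- sum(da & !db)
  n01 <- sum(!da & db)
  list(contingency = Contingency(n11, n10, n01, N - n11 - n10 - n01),
       shared = sort(colnames(x@incidence)[da & db]))
})
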