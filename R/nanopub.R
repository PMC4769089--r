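## Nanopublications: one association per publication, encoded as four
## named RDF graphs (head, assertion, provenance, publication info).
##
## The default implicit-association layout totals 20 triples:
##   head 4 (nanopub typed + links to its three parts)
##   assertion 7 (association node typed, linked to gene, disease and a
##                typed percentile value, labelled)
##   provenance 4 (generating activity typed, corpus snapshot used and
##                 derived from)
##   pubinfo 5 (created, creator, license, version, creating tool)
## Predicate and class URIs come from a configurable vocabulary table;
## the defaults lean on SIO, PROV-O, DCTerms and PAV plus a small package
## namespace for terms those ontologies do not provide.

.lw <- "http://purl.example.org/litwas/vocab#"

#' Default vocabulary table for nanopublication output
#'
#' Named character vector of class/predicate URIs; pass a modified copy
#' via the \code{vocab} argument of the constructors to re-map any term.
#'
#' @param overrides named character vector replacing individual entries.
#' @return named character vector of URIs.
#' @export
nanopubVocab <- function(overrides = character()) {
  v <- c(
    rdf_type = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    rdfs_label = "http://www.w3.org/2000/01/rdf-schema#label",
    np_Nanopublication = "http://www.nanopub.org/nschema#Nanopublication",
    np_hasAssertion = "http://www.nanopub.org/nschema#hasAssertion",
    np_hasProvenance = "http://www.nanopub.org/nschema#hasProvenance",
    np_hasPublicationInfo =
      "http://www.nanopub.org/nschema#hasPublicationInfo",
    sio_association = "http://semanticscience.org/resource/SIO_000897",
    sio_refers_to = "http://semanticscience.org/resource/SIO_000628",
    sio_has_measurement_value =
      "http://semanticscience.org/resource/SIO_000216",
    sio_has_value = "http://semanticscience.org/resource/SIO_000300",
    lw_PercentileRank = paste0(.lw, "PercentileRank"),
    lw_LiteratureCooccurrence = paste0(.lw, "LiteratureCooccurrence"),
    lw_ConceptProfileMatching = paste0(.lw, "ConceptProfileMatching"),
    lw_CooccurrenceIndexing = paste0(.lw, "CooccurrenceIndexing"),
    prov_wasGeneratedBy = "http://www.w3.org/ns/prov#wasGeneratedBy",
    prov_wasDerivedFrom = "http://www.w3.org/ns/prov#wasDerivedFrom",
    prov_used = "http://www.w3.org/ns/prov#used",
    cito_citesAsEvidence = "http://purl.org/spar/cito/citesAsEvidence",
    dct_created = "http://purl.org/dc/terms/created",
    dct_creator = "http://purl.org/dc/terms/creator",
    dct_license = "http://purl.org/dc/terms/license",
    pav_version = "http://purl.org/pav/version",
    pav_createdBy = "http://purl.org/pav/createdBy",
    xsd_double = "http://www.w3.org/2001/XMLSchema#double",
    xsd_dateTime = "http://www.w3.org/2001/XMLSchema#dateTime")
  if (length(overrides)) v[names(overrides)] <- overrides
  v
}

#' Default run metadata for nanopublication output
#'
#' @param runId identifier of the LWAS run; part of every minted URI, so
#'   URI minting is injective over (pair, run id).
#' @param ... replacements for any of: baseUri, conceptBase, corpusUri,
#'   creator, created, license, version, tool, xrefBases (named vector
#'   prefix -> URI base).
#' @return list of metadata fields.
#' @export
nanopubMeta <- function(runId = "run1", ...) {
  meta <- list(
    runId = runId,
    baseUri = "http://purl.example.org/litwas/",
    conceptBase = "http://purl.example.org/litwas/concept/",
    corpusUri = "http://purl.example.org/litwas/corpus/snapshot",
    creator = "http://purl.example.org/litwas/agent/lwas-pipeline",
    created = "2016-01-01T00:00:00Z",
    license = "http://creativecommons.org/publicdomain/zero/1.0/",
    version = "1.0",
    tool = "http://purl.example.org/litwas/tool",
    xrefBases = c(
      UMLS = "http://linkedlifedata.com/resource/umls/id/",
      OMIM = "http://purl.bioontology.org/ontology/OMIM/",
      EG = "http://identifiers.org/ncbigene/",
      GO = "http://purl.obolibrary.org/obo/GO_",
      MESH = "http://id.nlm.nih.gov/mesh/"))
  dots <- list(...)
  meta[names(dots)] <- dots
  meta
}

.uri <- function(x) paste0("<", x, ">")

.lit <- function(x, datatype = NULL) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  out <- paste0("\"", x, "\"")
  if (!is.null(datatype)) out <- paste0(out, "^^", .uri(datatype))
  out
}

.num_lit <- function(x, datatype)
  paste0("\"", format(x, scientific = FALSE, trim = TRUE), "\"^^",
         .uri(datatype))

## resolvable URI of a concept from its first xref, else the concept base
.concept_uri <- function(id, thesaurus, meta) {
  row <- match(id, thesaurus@concepts$concept_id)
  if (is.na(row)) stop("unknown concept: ", id)
  xr <- thesaurus@concepts$xrefs[row]
  if (nzchar(xr)) {
    first <- strsplit(xr, "|", fixed = TRUE)[[1L]][1L]
    parts <- strsplit(first, ":", fixed = TRUE)[[1L]]
    base <- if (parts[1L] %in% names(meta$xrefBases))
      meta$xrefBases[[parts[1L]]] else NULL
    if (is.null(base))
      stop("configuration error: no URI base for xref prefix '",
           parts[1L], "'")
    return(paste0(base, paste(parts[-1L], collapse = ":")))
  }
  if (is.null(meta$conceptBase))
    stop("configuration error: conceptBase missing and concept '", id,
         "' has no xrefs")
  paste0(meta$conceptBase, id)
}

.np_parts <- function(np_uri) {
  c(head = paste0(np_uri, "#head"),
    assertion = paste0(np_uri, "#assertion"),
    provenance = paste0(np_uri, "#provenance"),
    pubinfo = paste0(np_uri, "#pubinfo"))
}

.triples <- function(...) {
  rows <- list(...)
  matrix(unlist(rows), ncol = 3L, byrow = TRUE)
}

.head_graph <- function(np_uri, parts, v) {
  .triples(
    c(.uri(np_uri), .uri(v[["rdf_type"]]),
      .uri(v[["np_Nanopublication"]])),
    c(.uri(np_uri), .uri(v[["np_hasAssertion"]]),
      .uri(parts[["assertion"]])),
    c(.uri(np_uri), .uri(v[["np_hasProvenance"]]),
      .uri(parts[["provenance"]])),
    c(.uri(np_uri), .uri(v[["np_hasPublicationInfo"]]),
      .uri(parts[["pubinfo"]])))
}

.prov_graph <- function(parts, activity_type, meta, v) {
  act <- paste0(sub("#provenance$", "", parts[["provenance"]]),
                "#activity")
  .triples(
    c(.uri(parts[["assertion"]]), .uri(v[["prov_wasGeneratedBy"]]),
      .uri(act)),
    c(.uri(act), .uri(v[["rdf_type"]]), .uri(activity_type)),
    c(.uri(act), .uri(v[["prov_used"]]), .uri(meta$corpusUri)),
    c(.uri(parts[["assertion"]]), .uri(v[["prov_wasDerivedFrom"]]),
      .uri(meta$corpusUri)))
}

.pubinfo_graph <- function(np_uri, meta, v) {
  .triples(
    c(.uri(np_uri), .uri(v[["dct_created"]]),
      .lit(meta$created, v[["xsd_dateTime"]])),
    c(.uri(np_uri), .uri(v[["dct_creator"]]), .uri(meta$creator)),
    c(.uri(np_uri), .uri(v[["dct_license"]]), .uri(meta$license)),
    c(.uri(np_uri), .uri(v[["pav_version"]]), .lit(meta$version)),
    c(.uri(np_uri), .uri(v[["pav_createdBy"]]), .uri(meta$tool)))
}

#' Nanopublication of one implicit gene-disease association
#'
#' Asserts that a gene is associated with a disease with relative strength
#' given by its LWAS percentile rank.  The default layout totals exactly
#' 20 triples across the four named graphs.
#'
#' @param pair character vector (gene id, disease id).
#' @param percentile percentile rank in \[0, 100\].
#' @param thesaurus a \linkS4class{ConceptThesaurus} (for xrefs/labels).
#' @param meta metadata list from \code{\link{nanopubMeta}}.
#' @param vocab vocabulary table from \code{\link{nanopubVocab}}.
#' @return a \linkS4class{Nanopub}.
#' @export
makeAssociationNanopub <- function(pair, percentile,
                                   thesaurus, meta = nanopubMeta(),
                                   vocab = nanopubVocab()) {
  stopifnot(length(pair) == 2L)
  if (is.na(percentile) || percentile < 0 || percentile > 100)
    stop("percentile must lie in [0, 100]")
  v <- vocab
  np_uri <- paste0(meta$baseUri, "np/", meta$runId, "/", pair[[1L]], "_",
                   pair[[2L]])
  parts <- .np_parts(np_uri)
  assoc <- paste0(np_uri, "#association")
  val <- paste0(np_uri, "#percentile")
  g_uri <- .concept_uri(pair[[1L]], thesaurus, meta)
  d_uri <- .concept_uri(pair[[2L]], thesaurus, meta)
  lab <- sprintf("Association between %s and %s", pair[[1L]], pair[[2L]])
  assertion <- .triples(
    c(.uri(assoc), .uri(v[["rdf_type"]]), .uri(v[["sio_association"]])),
    c(.uri(assoc), .uri(v[["sio_refers_to"]]), .uri(g_uri)),
    c(.uri(assoc), .uri(v[["sio_refers_to"]]), .uri(d_uri)),
    c(.uri(assoc), .uri(v[["sio_has_measurement_value"]]), .uri(val)),
    c(.uri(val), .uri(v[["rdf_type"]]), .uri(v[["lw_PercentileRank"]])),
    c(.uri(val), .uri(v[["sio_has_value"]]),
      .num_lit(percentile, v[["xsd_double"]])),
    c(.uri(assoc), .uri(v[["rdfs_label"]]), .lit(lab)))
  new("Nanopub", uri = np_uri,
      head = .head_graph(np_uri, parts, v),
      assertion = assertion,
      provenance = .prov_graph(parts, v[["lw_ConceptProfileMatching"]],
                               meta, v),
      pubinfo = .pubinfo_graph(np_uri, meta, v))
}

#' Nanopublications of explicit gene-disease co-occurrences
#'
#' One nanopublication per evidence document: each asserts a single
#' gene-disease co-occurrence and the id of the publication in which the
#' pair co-occurs.
#'
#' @param pair character vector (gene id, disease id).
#' @param docIds non-empty character vector of evidence document ids.
#' @param thesaurus a \linkS4class{ConceptThesaurus}.
#' @param meta,vocab see \code{\link{makeAssociationNanopub}}.
#' @return list of \linkS4class{Nanopub}, one per document.
#' @export
makeExplicitNanopub <- function(pair, docIds, thesaurus,
                                meta = nanopubMeta(),
                                vocab = nanopubVocab()) {
  stopifnot(length(pair) == 2L)
  if (!length(docIds)) stop("explicit nanopub needs at least one doc id")
  v <- vocab
  g_uri <- .concept_uri(pair[[1L]], thesaurus, meta)
  d_uri <- .concept_uri(pair[[2L]], thesaurus, meta)
  lapply(docIds, function(doc) {
    np_uri <- paste0(meta$baseUri, "np/", meta$runId, "/", pair[[1L]],
                     "_", pair[[2L]], "_", doc)
    parts <- .np_parts(np_uri)
    assoc <- paste0(np_uri, "#cooccurrence")
    assertion <- .triples(
      c(.uri(assoc), .uri(v[["rdf_type"]]),
        .uri(v[["lw_LiteratureCooccurrence"]])),
      c(.uri(assoc), .uri(v[["sio_refers_to"]]), .uri(g_uri)),
      c(.uri(assoc), .uri(v[["sio_refers_to"]]), .uri(d_uri)),
      c(.uri(assoc), .uri(v[["cito_citesAsEvidence"]]),
        .uri(paste0(meta$baseUri, "document/", doc))))
    new("Nanopub", uri = np_uri,
        head = .head_graph(np_uri, parts, v),
        assertion = assertion,
        provenance = .prov_graph(parts, v[["lw_CooccurrenceIndexing"]],
                                 meta, v),
        pubinfo = .pubinfo_graph(np_uri, meta, v))
  })
}

## ---------------------------------------------------------------------------
## Serialization (TriG / N-Quads) and parse-back
## ---------------------------------------------------------------------------

.np_quads <- function(np) {
  parts <- .np_parts(np@uri)
  gs <- npGraphs(np)
  do.call(rbind, lapply(names(gs), function(nm) {
    g <- gs[[nm]]
    if (!nrow(g)) return(NULL)
    cbind(g, parts[[nm]])
  }))
}

#' Serialize nanopublications to TriG or N-Quads
#'
#' Deterministic output: nanopubs in the order given, graphs in head /
#' assertion / provenance / pubinfo order, triples in layout order, so
#' identical input yields byte-identical files.
#'
#' @param nanopubs a \linkS4class{Nanopub} or list of them.
#' @param path output file.
#' @param format "trig" or "nquads".
#' @return \code{path}, invisibly.
#' @export
serializeNanopubs <- function(nanopubs, path,
                              format = c("trig", "nquads")) {
  format <- match.arg(format)
  if (methods::is(nanopubs, "Nanopub")) nanopubs <- list(nanopubs)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (format == "nquads") {
    for (np in nanopubs) {
      q <- .np_quads(np)
      if (!is.null(q))
        writeLines(paste(q[, 1L], q[, 2L], q[, 3L],
                         .uri(q[, 4L]), "."), con)
    }
  } else {
    for (np in nanopubs) {
      parts <- .np_parts(np@uri)
      gs <- npGraphs(np)
      for (nm in names(gs)) {
        g <- gs[[nm]]
        writeLines(paste0(.uri(parts[[nm]]), " {"), con)
        if (nrow(g))
          writeLines(paste0("  ", g[, 1L], " ", g[, 2L], " ", g[, 3L],
                            " ."), con)
        writeLines("}", con)
      }
    }
  }
  invisible(path)
}

## tokenize one statement into RDF terms (URIs and literals)
.rdf_terms <- function(line) {
  pat <- paste0("<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"",
                "(?:\\^\\^<[^>]*>|@[A-Za-z-]+)?")
  m <- gregexpr(pat, line, perl = TRUE)[[1L]]
  if (m[1L] == -1L) character() else regmatches(line, list(m))[[1L]]
}

#' Parse a TriG or N-Quads file written by \code{\link{serializeNanopubs}}
#'
#' Reads the canonical named-graph subset this package emits and
#' reassembles \linkS4class{Nanopub} objects (grouped by nanopub URI,
#' graphs identified by their #head / #assertion / #provenance /
#' #pubinfo suffix).
#'
#' @param path input file.
#' @param format "trig" or "nquads".
#' @return list of \linkS4class{Nanopub}.
#' @export
parseNanopubs <- function(path, format = c("trig", "nquads")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  quads <- list()
  if (format == "nquads") {
    for (ln in lines) {
      if (!nzchar(trimws(ln))) next
      tm <- .rdf_terms(ln)
      if (length(tm) != 4L) stop("malformed N-Quads line: ", ln)
      quads[[length(quads) + 1L]] <-
        c(tm[1:3], sub("^<(.*)>$", "\\1", tm[4L]))
    }
  } else {
    graph <- NULL
    for (ln in lines) {
      t <- trimws(ln)
      if (!nzchar(t)) next
      if (t == "}") { graph <- NULL; next }
      if (endsWith(t, "{")) {
        graph <- sub("^<(.*)> \\{$", "\\1", t)
        next
      }
      tm <- .rdf_terms(t)
      if (length(tm) != 3L || is.null(graph))
        stop("malformed TriG line: ", ln)
      quads[[length(quads) + 1L]] <- c(tm, graph)
    }
  }
  if (!length(quads)) return(list())
  q <- do.call(rbind, quads)
  np_uri <- sub("#(head|assertion|provenance|pubinfo)$", "", q[, 4L])
  part <- sub("^.*#", "", q[, 4L])
  out <- lapply(unique(np_uri), function(u) {
    pick <- function(p) {
      rows <- q[np_uri == u & part == p, 1:3, drop = FALSE]
      matrix(rows, ncol = 3L)
    }
    new("Nanopub", uri = u, head = pick("head"),
        assertion = pick("assertion"), provenance = pick("provenance"),
        pubinfo = pick("pubinfo"))
  })
  out
}

## ---------------------------------------------------------------------------
## CSV export
## ---------------------------------------------------------------------------

#' Export LWAS associations as CSV
#'
#' Header plus one row per scored pair: gene_id, disease_id, score,
#' percentile, explicit (0/1), n_overlap.  Floats carry 17 significant
#' digits so \code{\link{readAssociationsCSV}} reloads them bit-exact.
#'
#' @param run an \linkS4class{LwasRun} (or its results data.frame).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportAssociationsCSV <- function(run, path) {
  res <- if (methods::is(run, "LwasRun")) run@results else run
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("gene_id,disease_id,score,percentile,explicit,n_overlap", con)
  if (nrow(res))
    writeLines(sprintf("%s,%s,%.17g,%.17g,%d,%d", res$gene_id,
                       res$disease_id, res$score,
                       if (is.null(res$percentile)) NA_real_ else
                         res$percentile,
                       as.integer(res$explicit),
                       as.integer(res$n_overlap)), con)
  invisible(path)
}

#' Reload an associations CSV written by \code{\link{exportAssociationsCSV}}
#' @param path CSV file.
#' @return data.frame mirroring the run results.
#' @export
readAssociationsCSV <- function(path) {
  tab <- data.table::fread(path, sep = ",", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = 1:2,
                                             numeric = 3:4,
                                             integer = 5:6))
  tab$explicit <- tab$explicit == 1L
  tab
}
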