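np_thesaurus <- function() {
  conceptThesaurus(data.frame(
    concept_id = c("G1", "D1", "G2", "D2", "NOX"),
    semantic_type = c("gene", "disease", "gene", "disease", "gene"),
    term = c("geneA1", "disA1", "geneB1", "disB1", "noxref1"),
    is_preferred = 1L,
    xrefs = c("EG:101", "OMIM:210600", "EG:102", "UMLS:C0004943", ""),
    stringsAsFactors = FALSE))
}

test_that("the default implicit-association layout totals 20 triples", {
  th <- np_thesaurus()
  np <- makeAssociationNanopub(c("G1", "D1"), 99.9, th)
  expect_equal(tripleCount(np), 20L)
  gs <- npGraphs(np)
  expect_named(gs, c("head", "assertion", "provenance", "pubinfo"))
  expect_equal(nrow(gs$head), 4L)
  expect_equal(nrow(gs$assertion), 7L)
  expect_equal(nrow(gs$provenance), 4L)
  expect_equal(nrow(gs$pubinfo), 5L)
  # the head links the nanopub to each of its three parts
  expect_true(all(grepl(np@uri, gs$head[, 1], fixed = TRUE)))
  # the asserted percentile value appears as a typed literal
  expect_true(any(grepl("\"99.9\"", gs$assertion[, 3], fixed = TRUE)))
  # gene and disease referenced through their xref-based URIs
  expect_true(any(grepl("ncbigene/101", gs$assertion[, 3])))
  expect_true(any(grepl("OMIM/210600", gs$assertion[, 3])))
})

test_that("percentile bounds and xref configuration are enforced", {
  th <- np_thesaurus()
  expect_s4_class(makeAssociationNanopub(c("G1", "D1"), 0, th), "Nanopub")
  expect_error(makeAssociationNanopub(c("G1", "D1"), 101, th),
               "\\[0, 100\\]")
  expect_error(makeAssociationNanopub(c("G1", "D1"), -1, th),
               "\\[0, 100\\]")
  # unknown xref prefix is a configuration error
  meta <- nanopubMeta(xrefBases = c(ZZZ = "http://example.org/zzz/"))
  expect_error(makeAssociationNanopub(c("G1", "D1"), 50, th, meta = meta),
               "no URI base")
  # a concept without xrefs falls back to the concept base URI
  np <- makeAssociationNanopub(c("NOX", "D1"), 50, th)
  expect_true(any(grepl("concept/NOX", np@assertion[, 3])))
})

test_that("URIs are deterministic and injective over (pair, run id)", {
  th <- np_thesaurus()
  np1 <- makeAssociationNanopub(c("G1", "D1"), 10, th)
  np1b <- makeAssociationNanopub(c("G1", "D1"), 10, th)
  np2 <- makeAssociationNanopub(c("G2", "D2"), 10, th)
  np3 <- makeAssociationNanopub(c("G1", "D1"), 10, th,
                                meta = nanopubMeta(runId = "run2"))
  expect_identical(np1@uri, np1b@uri)
  expect_false(np1@uri == np2@uri)
  expect_false(np1@uri == np3@uri)
  uris <- vapply(list(np1, np2, np3), function(x) x@uri, character(1))
  expect_equal(anyDuplicated(uris), 0L)
})

test_that("explicit nanopubs assert one co-occurrence per evidence document", {
  th <- np_thesaurus()
  nps <- makeExplicitNanopub(c("G1", "D1"), c("pm1", "pm2", "pm3"), th)
  expect_length(nps, 3L)
  for (i in seq_along(nps)) {
    expect_true(any(grepl(paste0("document/pm", i), nps[[i]]@assertion)))
    expect_gte(nrow(nps[[i]]@head), 4L)
  }
  one <- makeExplicitNanopub(c("G1", "D1"), "pm9", th)
  expect_length(one, 1L)
  expect_error(makeExplicitNanopub(c("G1", "D1"), character(), th),
               "at least one doc")
})

test_that("TriG and N-Quads round-trip the graph sets losslessly", {
  th <- np_thesaurus()
  nps <- c(list(makeAssociationNanopub(c("G1", "D1"), 97.5, th)),
           makeExplicitNanopub(c("G2", "D2"), c("pm1", "pm2"), th))
  for (fmt in c("trig", "nquads")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    serializeNanopubs(nps, path, format = fmt)
    back <- parseNanopubs(path, format = fmt)
    expect_length(back, length(nps))
    for (i in seq_along(nps)) {
      expect_equal(back[[i]]@uri, nps[[i]]@uri)
      got <- npGraphs(back[[i]])
      want <- npGraphs(nps[[i]])
      for (nm in names(want))
        expect_equal(unname(got[[nm]]), unname(want[[nm]]), info = fmt)
    }
    # serialize -> parse -> serialize is byte-stable
    path2 <- withr::local_tempfile(fileext = paste0(".", fmt))
    serializeNanopubs(back, path2, format = fmt)
    expect_identical(readLines(path2), readLines(path))
  }
  expect_error(serializeNanopubs(nps, tempfile(), format = "turtle"))
})

test_that("serialization is deterministic and handles the empty set", {
  th <- np_thesaurus()
  nps <- list(makeAssociationNanopub(c("G1", "D1"), 42, th))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  serializeNanopubs(nps, p1, "trig")
  serializeNanopubs(nps, p2, "trig")
  expect_identical(readLines(p1), readLines(p2))
  p0 <- withr::local_tempfile()
  serializeNanopubs(list(), p0, "nquads")
  expect_length(parseNanopubs(p0, "nquads"), 0L)
  # one nanopub yields exactly four named graphs on parse-back
  q <- readLines(p1)
  opens <- grep("\\{$", q, value = TRUE)
  expect_length(opens, 4L)
})

test_that("emitted N-Quads parse with a standard RDF quad parser", {
  python <- Sys.which("python")
  th <- np_thesaurus()
  nps <- c(list(makeAssociationNanopub(c("G1", "D1"), 88.8, th)),
           makeExplicitNanopub(c("G2", "D2"), "pm1", th))
  path <- tempfile(fileext = ".nq")
  on.exit(unlink(path))
  serializeNanopubs(nps, path, format = "nquads")
  code <- paste0(
    "import sys\n",
    "import rdflib\n",
    "ds = rdflib.Dataset()\n",
    "ds.parse('", path, "', format='nquads')\n",
    "gs = [g for g in ds.graphs() if len(g)]\n",
    "print(len(gs), sum(len(g) for g in gs))\n")
  res <- suppressWarnings(system2(python, c("-c", shQuote(code)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0,
              info = paste(res, collapse = " "))
  nums <- as.integer(strsplit(tail(res, 1), " ")[[1]])
  expect_equal(nums[1], 8L)             # four named graphs per nanopub
  expect_equal(nums[2], sum(vapply(nps, tripleCount, integer(1))))
})

test_that("the associations CSV reloads to full float precision", {
  g <- generateCorpus(demoSynthSpec())
  idx <- buildConceptIndex(g$corpus, g$thesaurus)
  run <- runLwas(idx, g$thesaurus)
  path <- withr::local_tempfile(fileext = ".csv")
  exportAssociationsCSV(run, path)
  back <- readAssociationsCSV(path)
  res <- lwasResults(run)
  expect_equal(nrow(back), nrow(res))
  expect_identical(back$score, res$score)
  expect_identical(back$percentile, res$percentile)
  expect_identical(back$gene_id, res$gene_id)
  expect_identical(back$explicit, res$explicit)

  # empty run: header-only file
  p0 <- withr::local_tempfile(fileext = ".csv")
  exportAssociationsCSV(data.frame(gene_id = character(),
                                   disease_id = character(),
                                   score = numeric(),
                                   percentile = numeric(),
                                   explicit = logical(),
                                   n_overlap = integer()), p0)
  expect_equal(length(readLines(p0)), 1L)
})
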