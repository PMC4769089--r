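# small fully-profiled world: every gene and disease in >= minDocs docs
pairworld <- function(n_genes = 3, n_diseases = 4, min_docs = 2) {
  gid <- sprintf("G%02d", seq_len(n_genes))
  did <- sprintf("D%02d", seq_len(n_diseases))
  sets <- list()
  for (g in gid) for (r in seq_len(min_docs))
    sets[[length(sets) + 1L]] <- c(g, "Y1")
  for (d in did) for (r in seq_len(min_docs))
    sets[[length(sets) + 1L]] <- c(d, "Y1")
  # filler documents keep the hub concept informative (a concept present
  # in every document has zero entropy and hence zero weight)
  for (r in 1:4) sets[[length(sets) + 1L]] <- "F1"
  th <- id_thesaurus(c(gid, did, "Y1", "F1"),
                     c(rep("gene", n_genes), rep("disease", n_diseases),
                       "other", "other"))
  corpus <- data.frame(
    doc_id = sprintf("d%03d", seq_along(sets)),
    title = vapply(sets, function(s) paste(tolower(s), collapse = " "),
                   character(1)),
    abstract = "",
    keywords = I(replicate(length(sets), character(), simplify = FALSE)),
    date = NA_character_, stringsAsFactors = FALSE)
  list(thesaurus = th, corpus = corpus)
}

test_that("run counts satisfy the pair-universe invariants", {
  w <- pairworld(3, 4, min_docs = 2)
  idx <- buildConceptIndex(w$corpus, w$thesaurus)
  run <- runLwas(idx, w$thesaurus, minDocs = 2)
  expect_equal(run@pairsTotal, 12)
  expect_equal(run@pairsScored, 12)
  expect_equal(run@pairsUnbuildable, 0)
  expect_equal(nrow(lwasResults(run)), 12)
  # every pair shares the hub concept Y1, so all scores are positive
  expect_true(all(lwasResults(run)$score > 0))

  # one gene below the cutoff removes one row of the matrix
  run5 <- runLwas(idx, w$thesaurus, minDocs = 3)
  expect_equal(run5@pairsScored, 0)
  w2 <- pairworld(3, 4, min_docs = 5)
  idx2 <- buildConceptIndex(w2$corpus, w2$thesaurus)
  corpus3 <- w2$corpus[-(1:3), ]  # G01 drops to 2 docs
  idx3 <- buildConceptIndex(corpus3, w2$thesaurus)
  run3 <- runLwas(idx3, w2$thesaurus, minDocs = 5)
  expect_equal(run3@pairsUnbuildable, 4)
  expect_equal(run3@pairsScored, 8)

  th_nogene <- id_thesaurus("D01", "disease")
  expect_error(runLwas(idx, th_nogene), "gene and disease")
})

test_that("the thesaurus-scale pair arithmetic is exact", {
  run <- LwasRun(nGenes = 19113, nDiseases = 21847,
                 pairsScored = 204072376, nExplicit = 1479895)
  expect_identical(run@pairsTotal, 417561711)
  expect_identical(run@pairsUnbuildable, 213489335)
  ef <- explicitFraction(run)
  expect_identical(unname(ef["n_explicit"]), 1479895)
  expect_equal(round(unname(ef["fraction_pct"]), 2), 0.73)
})

test_that("explicit fraction covers the degenerate ends", {
  r0 <- LwasRun(nGenes = 2, nDiseases = 2, pairsScored = 4, nExplicit = 0)
  expect_equal(unname(explicitFraction(r0)["fraction_pct"]), 0)
  r1 <- LwasRun(nGenes = 2, nDiseases = 2, pairsScored = 4, nExplicit = 4)
  expect_equal(unname(explicitFraction(r1)["fraction_pct"]), 100)
  expect_error(LwasRun(nGenes = 2, nDiseases = 2, pairsScored = 4,
                       nExplicit = 5), "exceed")
})

test_that("explicit flags in a run match per-pair reclassification", {
  g <- generateCorpus(demoSynthSpec())
  idx <- buildConceptIndex(g$corpus, g$thesaurus)
  run <- runLwas(idx, g$thesaurus)
  res <- lwasResults(run)
  for (i in seq_len(nrow(res))) {
    ex <- classifyExplicit(idx, res$gene_id[i], res$disease_id[i])
    expect_equal(res$explicit[i], ex$explicit)
    expect_equal(res$n_cooccurrences[i], length(ex$evidence_docs))
  }
  ef <- explicitFraction(run)
  expect_equal(unname(ef["n_explicit"]), sum(res$explicit))
})

test_that("abundance distributions sort by count then id and match recounts", {
  th <- id_thesaurus(c("A1", "A2", "A3"), rep("gene", 3))
  sets <- c(replicate(5, "A1", simplify = FALSE),
            replicate(2, "A2", simplify = FALSE),
            replicate(2, "A3", simplify = FALSE))
  corpus <- data.frame(
    doc_id = sprintf("d%d", seq_along(sets)),
    title = vapply(sets, tolower, character(1)), abstract = "",
    keywords = I(replicate(length(sets), character(), simplify = FALSE)),
    date = NA_character_, stringsAsFactors = FALSE)
  idx <- buildConceptIndex(corpus, th)
  ab <- abundanceDistribution(idx, th, "gene")
  expect_equal(ab$concept_id, c("A1", "A2", "A3"))
  expect_equal(ab$doc_count, c(5, 2, 2))
  expect_equal(nrow(abundanceDistribution(idx, th, "disease")), 0L)

  # brute-force recount over the raw documents
  for (i in seq_len(nrow(ab)))
    expect_equal(ab$doc_count[i],
                 sum(vapply(sets, function(s)
                   ab$concept_id[i] %in% s, logical(1))))
})

test_that("coverage fraction finds the smallest covering prefix", {
  unif <- data.frame(concept_id = sprintf("c%d", 1:10), doc_count = 3)
  expect_equal(coverageFraction(unif, 0.8), 0.8)
  one <- data.frame(concept_id = sprintf("c%d", 1:5),
                    doc_count = c(9, 0, 0, 0, 0))
  expect_equal(coverageFraction(one, 0.8), 1 / 5)
  expect_error(coverageFraction(unif, 0), "in \\(0, 1\\]")
  expect_error(coverageFraction(unif, 1.2), "in \\(0, 1\\]")
  expect_error(coverageFraction(unif[0, ], 0.5), "empty")

  # Zipf-skewed synthetic abundance: direct summation oracle
  g <- generateCorpus(synthSpec(nBackgroundConcepts = 200, seed = 42))
  ab <- g$truth$abundance
  ab <- ab[order(-ab$doc_count, ab$concept_id), ]
  got <- coverageFraction(ab, 0.8)
  k <- which(cumsum(ab$doc_count) >= 0.8 * sum(ab$doc_count))[1]
  expect_equal(got, k / nrow(ab))
  expect_lt(got, 0.8)   # skew: fewer concepts cover 80% of mentions
})

test_that("a time-sliced run never sees documents after the cutoff", {
  spec <- synthSpec(seed = 5)
  g <- generateCorpus(spec)
  cutoff <- "2008-12-31"
  idx_cut <- buildConceptIndex(g$corpus, g$thesaurus, until = cutoff)
  expect_true(all(idx_cut@dates <= as.Date(cutoff)))
  manual <- g$corpus[as.Date(g$corpus$date) <= as.Date(cutoff), ]
  idx_manual <- buildConceptIndex(manual, g$thesaurus)
  expect_equal(nDocs(idx_cut), nDocs(idx_manual))
  run_cut <- runLwas(idx_cut, g$thesaurus, until = cutoff)
  run_manual <- runLwas(idx_manual, g$thesaurus)
  expect_equal(lwasResults(run_cut)$score, lwasResults(run_manual)$score)
  expect_equal(lwasConfig(run_cut)$until, cutoff)
})

test_that("sampled-reference percentiles are seeded and recorded", {
  g <- generateCorpus(demoSynthSpec())
  idx <- buildConceptIndex(g$corpus, g$thesaurus)
  r1 <- runLwas(idx, g$thesaurus, percentileMode = "sampled",
                referenceSize = 3, seed = 99)
  r2 <- runLwas(idx, g$thesaurus, percentileMode = "sampled",
                referenceSize = 3, seed = 99)
  expect_equal(lwasResults(r1)$percentile, lwasResults(r2)$percentile)
  expect_equal(lwasConfig(r1)$seed, 99)
  expect_equal(lwasConfig(r1)$percentile_mode, "sampled")
})
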