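test_that("match score is the inner product over shared concepts", {
  pA <- profile_of("a", c(y1 = 0.5, y2 = 0.2))
  pB <- profile_of("b", c(y1 = 0.4, y3 = 0.1))
  m <- matchScore(pA, pB)
  expect_equal(m$score, 0.20)
  expect_equal(m$n_overlap, 1L)

  # disjoint profiles score zero with zero overlap, and only then
  pC <- profile_of("c", c(z9 = 0.9))
  m0 <- matchScore(pA, pC)
  expect_equal(m0$score, 0)
  expect_equal(m0$n_overlap, 0L)

  # symmetry
  expect_equal(matchScore(pB, pA)$score, m$score)
})

test_that("sparse match score equals a dense dot product on random profiles", {
  set.seed(55)
  dims <- sprintf("y%03d", 1:100)
  for (i in 1:100) {
    wa <- random_weights(dims)
    wb <- random_weights(dims)
    dense_a <- structure(numeric(100), names = dims)
    dense_b <- structure(numeric(100), names = dims)
    dense_a[names(wa)] <- wa
    dense_b[names(wb)] <- wb
    m <- matchScore(profile_of("a", wa), profile_of("b", wb))
    expect_equal(m$score, sum(dense_a * dense_b), tolerance = 1e-12)
    expect_equal(m$n_overlap, sum(dense_a > 0 & dense_b > 0))
  }
})

test_that("connecting-concept contributions are percentages summing to 100", {
  pA <- profile_of("a", c(y1 = 0.5))
  pB <- profile_of("b", c(y1 = 0.4))
  cc <- connectingConcepts(pA, pB)
  expect_equal(cc$concept_id, "y1")
  expect_equal(cc$contribution_pct, 100)

  pA2 <- profile_of("a", c(y1 = 0.5, y2 = 0.5))
  pB2 <- profile_of("b", c(y1 = 0.4, y2 = 0.1))
  cc2 <- connectingConcepts(pA2, pB2)      # products 0.2 and 0.05
  expect_equal(cc2$contribution_pct, c(80, 20))
  expect_equal(cc2$concept_id, c("y1", "y2"))
  expect_equal(cc2$rank, 1:2)

  # ties broken lexicographically by concept id
  pT <- profile_of("a", c(yb = 0.5, ya = 0.5))
  cct <- connectingConcepts(pT, profile_of("b", c(ya = 0.2, yb = 0.2)))
  expect_equal(cct$concept_id, c("ya", "yb"))

  expect_error(connectingConcepts(pA, profile_of("c", c(z = 1))),
               "zero match score")
})

test_that("contribution shares always sum to 100 on random overlapping profiles", {
  set.seed(56)
  dims <- sprintf("y%02d", 1:30)
  for (i in 1:50) {
    wa <- random_weights(dims, density = 0.5)
    wb <- random_weights(dims, density = 0.5)
    if (!length(intersect(names(wa), names(wb)))) next
    cc <- connectingConcepts(profile_of("a", wa), profile_of("b", wb))
    expect_equal(sum(cc$contribution_pct), 100, tolerance = 1e-9)
    expect_true(all(diff(cc$contribution_pct) <= 1e-12))
  }
})

test_that("explicit classification returns genuine evidence documents", {
  th <- id_thesaurus(c("G1", "D1", "Y1"), c("gene", "disease", "other"))
  corpus <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    title = c("g1 d1", "g1 y1", "y1 d1"), abstract = "",
    keywords = I(replicate(3, character(), simplify = FALSE)),
    date = NA_character_, stringsAsFactors = FALSE)
  idx <- buildConceptIndex(corpus, th)
  ex <- classifyExplicit(idx, "G1", "D1")
  expect_true(ex$explicit)
  expect_equal(ex$evidence_docs, "d1")
  # evidence documents genuinely contain both concepts
  for (d in ex$evidence_docs) {
    expect_true(all(c("G1", "D1") %in% docConcepts(idx, d)))
  }
  # the A-C pair of a pure bridge structure is implicit
  corpus2 <- corpus[2:3, ]
  idx2 <- buildConceptIndex(corpus2, th)
  ex2 <- classifyExplicit(idx2, "G1", "D1")
  expect_false(ex2$explicit)
  expect_length(ex2$evidence_docs, 0L)
})

test_that("percentile rank follows the strictly-below convention", {
  ref <- rep(1, 1500)
  expect_equal(percentileRank(2, ref), 100)   # above all references
  expect_equal(percentileRank(0.5, ref), 0)   # below all references
  expect_equal(percentileRank(1, ref), 0)     # ties rank below
  expect_error(percentileRank(1, numeric()), "empty")

  # monotone non-decreasing in the score for a fixed reference
  set.seed(57)
  ref <- runif(200)
  scores <- sort(runif(50))
  pr <- percentileRank(scores, ref)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(pr >= 0 & pr <= 100))
  # agrees with the naive count
  for (s in scores[1:10])
    expect_equal(percentileRank(s, ref), 100 * sum(ref < s) / length(ref))
})

test_that("candidate ranking recovers the planted bridge gene first", {
  g <- generateCorpus(synthSpec(nGenes = 4, nDiseases = 1,
                                nBridgeConcepts = 1,
                                nBackgroundConcepts = 20,
                                noiseRate = 0,
                                plantedBridges = data.frame(
                                  gene = "G02", bridge = "Y01",
                                  disease = "D01"),
                                plantedExplicit = data.frame(
                                  gene = character(),
                                  disease = character()),
                                seed = 9))
  # give unbridged genes some literature so they are scored at all
  idx <- buildConceptIndex(g$corpus, g$thesaurus)
  run <- runLwas(idx, g$thesaurus, minDocs = 1)
  ranked <- rankCandidates(run, "D01", topN = 10)
  expect_equal(ranked$concept_id[1], "G02")
  expect_false(ranked$explicit[1])
  expect_equal(ranked$evidence_doc_ids[1], "")
  # the bridge concept is the top connecting concept for the implicit hit
  expect_equal(ranked$top_connecting_concept[1], "Y01")
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  expect_error(rankCandidates(run, "NOPE"), "unknown concept")
})

test_that("ranking is invariant under input permutation and ties break by id", {
  pA <- profile_of("a", c(y1 = 0.3))
  res <- data.frame(gene_id = c("G2", "G1", "G3"), disease_id = "D1",
                    score = c(0.5, 0.5, 0.9), n_overlap = 1,
                    explicit = FALSE, n_cooccurrences = 0,
                    percentile = c(10, 10, 90),
                    stringsAsFactors = FALSE)
  th <- id_thesaurus(c("G1", "G2", "G3", "D1"),
                     c("gene", "gene", "gene", "disease"))
  idx <- buildConceptIndex(data.frame(
    doc_id = "d1", title = "g1", abstract = "",
    keywords = I(list(character())), date = NA_character_,
    stringsAsFactors = FALSE), th)
  mk <- function(r) {
    run <- LwasRun(nGenes = 3, nDiseases = 1, pairsScored = 3,
                   results = r, index = idx, thesaurus = th)
    rankCandidates(run, "D1")$concept_id
  }
  expect_equal(mk(res), c("G3", "G1", "G2"))
  expect_equal(mk(res[c(3, 1, 2), ]), c("G3", "G1", "G2"))
})
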