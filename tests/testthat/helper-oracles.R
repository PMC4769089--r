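# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately recompute quantities from first principles
# (dense algebra, raw document scans, direct entropy sums) so they never
# share code with the implementation paths they check.

# symmetric uncertainty from the full 2x2 joint distribution, via plain
# entropy sums over the joint and both margins
su_oracle <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  joint <- c(n11, n10, n01, n00) / n
  px <- c(n11 + n10, n01 + n00) / n
  py <- c(n11 + n01, n10 + n00) / n
  H <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hx <- H(px); hy <- H(py); hxy <- H(joint)
  if (hx + hy == 0) return(0)
  2 * (hx + hy - hxy) / (hx + hy)
}

# a thesaurus whose terms are the concept ids themselves (digits keep the
# stemmer away), one concept per id
id_thesaurus <- function(ids, types = NULL) {
  if (is.null(types)) types <- rep("other", length(ids))
  conceptThesaurus(data.frame(
    concept_id = ids, semantic_type = types, term = tolower(ids),
    is_preferred = 1L, xrefs = "", stringsAsFactors = FALSE))
}

# random corpus over id-named concepts; returns the corpus data.frame and
# the true per-document concept sets
random_corpus <- function(n_docs, concept_ids, mean_tags = 3,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sets <- lapply(seq_len(n_docs), function(i) {
    k <- min(length(concept_ids), 1 + rpois(1, mean_tags - 1))
    sort(sample(concept_ids, k))
  })
  corpus <- data.frame(
    doc_id = sprintf("d%04d", seq_len(n_docs)),
    title = vapply(sets, function(s) paste(tolower(s), collapse = " "),
                   character(1)),
    abstract = "",
    keywords = I(replicate(n_docs, character(), simplify = FALSE)),
    date = NA_character_, stringsAsFactors = FALSE)
  list(corpus = corpus, sets = sets)
}

# brute-force contingency by scanning the raw document sets
contingency_oracle <- function(sets, a, b) {
  ina <- vapply(sets, function(s) a %in% s, logical(1))
  inb <- vapply(sets, function(s) b %in% s, logical(1))
  c(n11 = sum(ina & inb), n10 = sum(ina & !inb),
    n01 = sum(!ina & inb), n00 = sum(!ina & !inb))
}

# build a ConceptProfile directly from a named weight vector
profile_of <- function(seed, weights, n_docs = 100, min_docs = 5) {
  w <- weights[order(names(weights))]
  new("ConceptProfile", seed = seed, weights = w,
      builtFromNDocs = n_docs, minDocs = min_docs)
}

# random sparse profile over a shared dimension, as a named vector
random_weights <- function(dim_ids, density = 0.3) {
  keep <- runif(length(dim_ids)) < density
  if (!any(keep)) keep[sample.int(length(dim_ids), 1)] <- TRUE
  structure(runif(sum(keep)), names = dim_ids[keep])
}

# random valid contingency table (positive total)
random_table <- function(max_cell = 50) {
  repeat {
    cells <- rpois(4, sample(c(1, 5, 20), 1))
    if (sum(cells) > 0) return(cells)
  }
}
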