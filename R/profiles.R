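## Symmetric uncertainty weighting and concept profile assembly.
##
## The weight of concept y in the profile of seed x is the symmetric
## uncertainty coefficient U = 2*I(X;Y)/(H(X)+H(Y)) of the two binary
## per-document occurrence indicators, computed from the 2x2 contingency.
## Entropies are in bits with 0*log(0) := 0; the log base cancels in the
## ratio.  Profiles contain only concepts that actually co-occur with the
## seed (n11 >= 1): mutual information is also positive for anti-correlated
## pairs, but profile links model explicit co-occurrence.

.xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)

## vectorized over the four cell-count vectors
.su_weights <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  if (any(n <= 0)) stop("contingency total must be positive")
  if (any(c(n11, n10, n01, n00) < 0)) stop("negative contingency cell")
  px <- (n11 + n10) / n
  py <- (n11 + n01) / n
  hx <- -(.xlogx(px) + .xlogx(1 - px))
  hy <- -(.xlogx(py) + .xlogx(1 - py))
  hxy <- -(.xlogx(n11 / n) + .xlogx(n10 / n) + .xlogx(n01 / n) +
             .xlogx(n00 / n))
  denom <- hx + hy
  u <- ifelse(denom > 0, 2 * (denom - hxy) / denom, 0)
  u <- pmin(pmax(u, 0), 1)
  ifelse(n11 == 0, 0, u)
}

#' @param n10,n01,n00 remaining cell counts (numeric, recycled), used when
#'   \code{x} is the n11 count.
#' @rdname symmetricUncertainty
#' @export
#' @examples
#' symmetricUncertainty(Contingency(5, 5, 5, 85))
#' symmetricUncertainty(5, 0, 0, 95)   # identical indicators -> 1
#' symmetricUncertainty(1, 1, 1, 1)    # exact independence -> 0
setMethod("symmetricUncertainty", "numeric",
  function(x, n10, n01, n00, ...) .su_weights(x, n10, n01, n00))

#' @rdname symmetricUncertainty
#' @export
setMethod("symmetricUncertainty", "Contingency", function(x, ...)
  .su_weights(x@n11, x@n10, x@n01, x@n00))

#' Build the concept profile of a seed concept
#'
#' Computes the symmetric uncertainty weight of every concept co-occurring
#' with the seed in at least one document.  Seeds below the document
#' frequency cutoff get no profile (NULL): with fewer than \code{minDocs}
#' abstracts the co-occurrence statistics are too sparse to be meaningful.
#' The seed itself is included with weight 1 (the self pair has identical
#' indicators), so endpoint concepts participate in profile overlaps.
#'
#' @param index a \linkS4class{ConceptIndex}.
#' @param seed concept id (must exist in the index's thesaurus rows).
#' @param minDocs minimum document frequency; default 5.
#' @return a \linkS4class{ConceptProfile}, or NULL when the seed is below
#'   the cutoff.
#' @export
buildProfile <- function(index, seed, minDocs = 5) {
  if (!seed %in% rownames(index@incidence))
    stop("unknown seed concept: ", seed)
  inc <- index@incidence
  df_seed <- sum(inc[seed, ])
  if (df_seed < minDocs) return(NULL)
  n <- ncol(inc)
  n11 <- as.numeric(inc %*% inc[seed, ])       # co-counts with every concept
  names(n11) <- rownames(inc)
  keep <- n11 > 0
  n11 <- n11[keep]
  dfy <- Matrix::rowSums(inc)[keep]
  n10 <- df_seed - n11
  n01 <- dfy - n11
  w <- .su_weights(n11, n10, n01, n - n11 - n10 - n01)
  w <- w[w > 0]
  w <- w[order(names(w))]
  new("ConceptProfile", seed = seed, weights = w,
      builtFromNDocs = as.numeric(n), minDocs = as.numeric(minDocs))
}

#' Build profiles for many seeds
#'
#' @param index a \linkS4class{ConceptIndex}.
#' @param seeds concept ids; default all indexed concepts.
#' @param minDocs document frequency cutoff (default 5).
#' @return named list of \linkS4class{ConceptProfile}; seeds below the
#'   cutoff are absent from the list.
#' @export
buildProfiles <- function(index, seeds = NULL, minDocs = 5) {
  if (is.null(seeds)) {
    df <- Matrix::rowSums(index@incidence)
    seeds <- names(df)[df >= minDocs]
  }
  out <- lapply(seeds, function(s) buildProfile(index, s, minDocs))
  names(out) <- seeds
  out[!vapply(out, is.null, logical(1))]
}

#' Write a profile store (sparse triplet TSV)
#'
#' Columns seed_id, concept_id, weight; weights printed with 17
#' significant digits so the reload is bit-exact.  Corpus size and cutoff
#' are carried in a comment header.
#'
#' @param profiles named list of \linkS4class{ConceptProfile}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  nd <- if (length(profiles)) profiles[[1L]]@builtFromNDocs else 0
  md <- if (length(profiles)) profiles[[1L]]@minDocs else 5
  writeLines(sprintf("# n_docs=%s min_docs=%s", format(nd), format(md)), con)
  writeLines("seed_id\tconcept_id\tweight", con)
  for (p in profiles[order(names(profiles))]) {
    w <- p@weights
    if (!length(w)) next
    writeLines(sprintf("%s\t%s\t%.17g", p@seed, names(w), w), con)
  }
  invisible(path)
}

#' Read a profile store written by \code{\link{writeProfiles}}
#' @param path TSV file.
#' @return named list of \linkS4class{ConceptProfile}.
#' @export
readProfiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[0-9.]+", hdr))[[1L]]
  nd <- as.numeric(meta[1L])
  md <- as.numeric(meta[2L])
  tab <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE,
                           colClasses = list(character = 1:2, numeric = 3),
                           data.table = FALSE)
  if (!nrow(tab)) return(structure(list(), names = character()))
  out <- lapply(split(tab, tab$seed_id), function(d) {
    w <- structure(d$weight, names = d$concept_id)
    w <- w[order(names(w))]
    new("ConceptProfile", seed = d$seed_id[1L], weights = w,
        builtFromNDocs = nd, minDocs = md)
  })
  out[order(names(out))]
}
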