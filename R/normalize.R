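## Term normalization: lowercase, strip punctuation, drop stop words, stem.
## All dictionary matching and homonym counting runs over this normal form,
## so the same function must be used on thesaurus terms and document text.

.suffix_rules <- c("ing", "ed", "ies", "es", "s", "e")

## Deterministic suffix stemmer. Longest matching suffix from the rule
## list is stripped provided >= 3 characters remain, and the rules are
## re-applied until a fixed point, which makes stemming (and hence
## normalizeTerm) idempotent. Tokens containing digits are identifiers
## and are never stemmed.
.stem_one <- function(tok) {
  if (grepl("[0-9]", tok)) return(tok)
  repeat {
    stripped <- FALSE
    for (suf in .suffix_rules) {
      ns <- nchar(suf)
      if (nchar(tok) - ns >= 3L && endsWith(tok, suf)) {
        tok <- substr(tok, 1L, nchar(tok) - ns)
        stripped <- TRUE
        break
      }
    }
    if (!stripped) return(tok)
  }
}

#' Normalize free text into matchable tokens
#'
#' Lowercases, replaces punctuation with spaces, splits on whitespace,
#' removes stop words, and stems each token.  The default stemmer strips
#' the suffixes ing/ed/ies/es/s/e (longest first, iterated to a fixed
#' point, minimum stem length 3; tokens containing digits are left alone).
#' The identity stemmer disables stemming.  Deterministic; an empty input
#' yields an empty token vector.
#'
#' @param term character scalar (or vector, normalized element-wise into a
#'   single token stream).
#' @param stopwords character vector of stop words, compared after
#'   lowercasing; defaults to the packaged English list.
#' @param stemmer "suffix" (default) or "identity".
#' @return character vector of normalized tokens.
#' @export
#' @examples
#' normalizeTerm("Seckel Syndrome", stopwords = character())
#' normalizeTerm("the ATR", stopwords = "the")
normalizeTerm <- function(term, stopwords = defaultStopwords(),
                          stemmer = c("suffix", "identity")) {
  stemmer <- match.arg(stemmer)
  if (length(term) == 0L) return(character())
  txt <- tolower(paste(term, collapse = " "))
  txt <- gsub("[^a-z0-9]+", " ", txt)
  toks <- strsplit(trimws(txt), " +")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(stopwords)) toks <- toks[!toks %in% tolower(stopwords)]
  if (stemmer == "suffix" && length(toks))
    toks <- vapply(toks, .stem_one, character(1), USE.NAMES = FALSE)
  toks
}

## Normal-form key of a whole term: its tokens joined by single spaces.
.norm_key <- function(term, stopwords, stemmer) {
  paste(normalizeTerm(term, stopwords, stemmer), collapse = " ")
}

#' Packaged English stop-word list
#'
#' A small general-English list shipped with the package; override by
#' passing your own vector to \code{\link{normalizeTerm}},
#' \code{\link{readThesaurus}} or \code{\link{buildConceptIndex}}.
#'
#' @return character vector.
#' @export
defaultStopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "litwas")
  if (!nzchar(path)) return(character())
  readLines(path, warn = FALSE)
}
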