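#' @import methods
#' @importFrom stats median rbinom runif
#' @importFrom utils head
NULL

#' @export
setGeneric("conceptIds", function(x, ...) standardGeneric("conceptIds"))

#' @export
setGeneric("docIds", function(x, ...) standardGeneric("docIds"))

#' @export
setGeneric("nConcepts", function(x, ...) standardGeneric("nConcepts"))

#' @export
setGeneric("nDocs", function(x, ...) standardGeneric("nDocs"))

#' @export
setGeneric("semanticTypes", function(x, ...) standardGeneric("semanticTypes"))

#' @export
setGeneric("homonymFrequencies", function(x, ...)
  standardGeneric("homonymFrequencies"))

#' @export
setGeneric("docFrequency", function(x, concept, ...)
  standardGeneric("docFrequency"))

#' @export
setGeneric("cooccurrence", function(x, a, b, ...)
  standardGeneric("cooccurrence"))

#' Symmetric uncertainty coefficient of a 2x2 co-occurrence table
#'
#' Normalized mutual information 2*I(X;Y)/(H(X)+H(Y)) of the two binary
#' per-document occurrence indicators, entropies in bits. See the method
#' for numeric arguments for the exact conventions.
#'
#' @param x a \linkS4class{Contingency}, or the n11 cell count (numeric,
#'   vectorized) when the remaining cells are given via \code{...}.
#' @param ... further arguments passed to methods.
#' @return numeric weight(s) in \[0, 1\].
#' @export
setGeneric("symmetricUncertainty", function(x, ...)
  standardGeneric("symmetricUncertainty"))

#' @export
setGeneric("seedConcept", function(x) standardGeneric("seedConcept"))

#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))

#' @export
setGeneric("profileSize", function(x) standardGeneric("profileSize"))

#' @export
setGeneric("lwasResults", function(x) standardGeneric("lwasResults"))

#' @export
setGeneric("lwasConfig", function(x) standardGeneric("lwasConfig"))

#' @export
setGeneric("npGraphs", function(x) standardGeneric("npGraphs"))

#' @export
setGeneric("tripleCount", function(x) standardGeneric("tripleCount"))
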