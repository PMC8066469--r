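#' @include AllGenerics.R
NULL

#' Construct an AnnotationMap
#'
#' @param lineages named list (protein id -> character vector of lineage
#'   ranks, least to most specific, e.g. Kingdom, Phylum, Class) or a named
#'   character vector of semicolon-delimited lineage strings.
#' @param goTerms named list (protein id -> character vector of GO ids).
#' @param lengths optional named numeric of amino-acid lengths.
#' @return a validated [AnnotationMap-class].
#' @export
AnnotationMap <- function(lineages = list(), goTerms = list(),
                          lengths = numeric()) {
  if (is.character(lineages)) {
    nm <- names(lineages)
    lineages <- strsplit(lineages, ";", fixed = TRUE)
    names(lineages) <- nm
  }
  lineages <- lapply(lineages, function(v) v[nzchar(v)])
  new("AnnotationMap", lineages = lineages, goTerms = goTerms,
      lengths = lengths)
}

#' Accessors for AnnotationMap
#'
#' \code{proteinLineage} and \code{proteinGO} return per-protein lineage rank
#' vectors and GO term sets (empty vectors for unmapped proteins);
#' \code{proteinLength} returns lengths (NA when unknown); \code{unannotated}
#' lists protein ids carrying neither a lineage nor a GO term.
#'
#' @param x an [AnnotationMap-class].
#' @param ids protein ids to look up.
#' @name annotationAccessors
#' @aliases proteinLineage proteinGO proteinLength unannotated
NULL

#' @rdname annotationAccessors
#' @export
setMethod("proteinLineage", "AnnotationMap", function(x, ids) {
  out <- x@lineages[ids]
  out[vapply(out, is.null, logical(1))] <- list(character())
  names(out) <- ids
  out
})

#' @rdname annotationAccessors
#' @export
setMethod("proteinGO", "AnnotationMap", function(x, ids) {
  out <- x@goTerms[ids]
  out[vapply(out, is.null, logical(1))] <- list(character())
  names(out) <- ids
  out
})

#' @rdname annotationAccessors
#' @export
setMethod("proteinLength", "AnnotationMap", function(x, ids) {
  out <- x@lengths[ids]
  names(out) <- ids
  out
})

#' @rdname annotationAccessors
#' @export
setMethod("unannotated", "AnnotationMap", function(x) {
  ids <- union(names(x@lineages), union(names(x@goTerms), names(x@lengths)))
  hasTax <- vapply(proteinLineage(x, ids), length, integer(1)) > 0
  hasGO <- vapply(proteinGO(x, ids), length, integer(1)) > 0
  ids[!hasTax & !hasGO]
})

setMethod("show", "AnnotationMap", function(object) {
  ids <- union(names(object@lineages), names(object@goTerms))
  cat(sprintf("AnnotationMap: %d protein(s); %d with lineage, %d with GO terms, %d with length\n",
              length(ids), sum(vapply(object@lineages, length, integer(1)) > 0),
              sum(vapply(object@goTerms, length, integer(1)) > 0),
              length(object@lengths)))
})

#' Restrict an annotation map to prokaryotic lineages
#'
#' Keeps proteins whose lineage root is one of the given kingdoms. Used to
#' exclude host (bivalve) and feed-algae contamination before functional
#' differential analysis.
#'
#' @param x an [AnnotationMap-class].
#' @param kingdoms lineage roots treated as prokaryotic.
#' @return character vector of retained protein ids.
#' @export
prokaryoteIds <- function(x, kingdoms = c("Bacteria", "Archaea")) {
  ids <- names(x@lineages)
  keep <- vapply(x@lineages, function(v) length(v) > 0 && v[1] %in% kingdoms,
                 logical(1))
  ids[keep]
}
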