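#' @include AllClasses.R
NULL

#' Omics layer of a table
#' @param x a [CountTable-class] object.
#' @return character scalar, \code{"metagenome"} or \code{"metaproteome"}.
#' @export
setGeneric("omicsLayer", function(x) standardGeneric("omicsLayer"))

#' Feature kind of a table
#' @param x a [CountTable-class] object.
#' @return character scalar: \code{"taxon"}, \code{"go_term"} or \code{"protein"}.
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' @rdname proteinAccessors
#' @export
setGeneric("proteinInfo", function(x) standardGeneric("proteinInfo"))

#' @rdname proteinAccessors
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname annotationAccessors
#' @export
setGeneric("proteinLineage", function(x, ids) standardGeneric("proteinLineage"))

#' @rdname annotationAccessors
#' @export
setGeneric("proteinGO", function(x, ids) standardGeneric("proteinGO"))

#' @rdname annotationAccessors
#' @export
setGeneric("proteinLength", function(x, ids) standardGeneric("proteinLength"))

#' @rdname annotationAccessors
#' @export
setGeneric("unannotated", function(x) standardGeneric("unannotated"))

#' Ground truth of a simulation
#' @param x a [SimulationConfig-class] or [SimulationTruth-class] object.
#' @return for a config, the derived [SimulationTruth-class]; accessors on a
#'   truth object return the stored matrices.
#' @export
setGeneric("simulationTruth", function(x) standardGeneric("simulationTruth"))
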