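#' @include AllGenerics.R
NULL

#' Construct a CountTable
#'
#' @param counts numeric matrix of nonnegative counts with feature ids as
#'   rownames and sample ids as colnames. All-zero rows are retained: absence
#'   is informative for presence/absence classification.
#' @param layer \code{"metagenome"} or \code{"metaproteome"}.
#' @param featureKind \code{"taxon"}, \code{"go_term"} or \code{"protein"}.
#' @param sampleData optional data.frame of per-sample metadata (see
#'   [readSampleMeta()]); matched to columns by \code{sample_id} and stored
#'   as \code{colData}.
#'
#' @return a validated [CountTable-class].
#' @examples
#' m <- matrix(c(2, 3, 5, 0, 1, 4), nrow = 3,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ct <- CountTable(m, layer = "metagenome", featureKind = "taxon")
#' counts(ct)
#' @export
CountTable <- function(counts, layer, featureKind, sampleData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sampleData)) {
    idx <- match(colnames(counts), sampleData$sample_id)
    if (anyNA(idx))
      stop("samples missing from metadata: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    cd <- S4Vectors::DataFrame(sampleData[idx, , drop = FALSE],
                               row.names = colnames(counts))
  }
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd)
  new("CountTable", se, layer = layer, featureKind = featureKind)
}

#' @rdname omicsLayer
#' @export
setMethod("omicsLayer", "CountTable", function(x) x@layer)

#' @rdname featureKind
#' @export
setMethod("featureKind", "CountTable", function(x) x@featureKind)

#' Count matrix of a CountTable
#' @param object a [CountTable-class].
#' @return the numeric feature x sample matrix.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "CountTable", function(object) assay(object, "counts"))

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d %s feature(s) x %d sample(s) [%s]\n",
              nrow(object), object@featureKind, ncol(object), object@layer))
  callNextMethod()
})

#' Per-sample metadata of a CountTable as a data.frame
#' @param x a [CountTable-class].
#' @return data.frame with one row per sample (possibly zero columns).
#' @export
sampleMeta <- function(x) {
  as.data.frame(colData(x))
}
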