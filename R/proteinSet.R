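#' @include AllGenerics.R
NULL

#' Construct a ProteinSet
#'
#' @param info data.frame with columns \code{protein_id}, \code{length}
#'   (amino acids), \code{probability} (ProteinProphet-style posterior,
#'   scored upstream), \code{unique_peptides} (pooled over all runs).
#' @param spectra numeric protein x run matrix of spectral counts; rows in
#'   the order of \code{info$protein_id}.
#' @return a validated [ProteinSet-class].
#' @export
ProteinSet <- function(info, spectra) {
  info <- as.data.frame(info)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  rownames(spectra) <- info$protein_id
  rownames(info) <- NULL
  new("ProteinSet", info = info, spectra = spectra)
}

#' Accessors for ProteinSet
#'
#' \code{proteinInfo} returns the per-protein table; \code{spectralCounts}
#' the protein x run count matrix.
#'
#' @param x a [ProteinSet-class].
#' @name proteinAccessors
#' @aliases proteinInfo spectralCounts
NULL

#' @rdname proteinAccessors
#' @export
setMethod("proteinInfo", "ProteinSet", function(x) x@info)

#' @rdname proteinAccessors
#' @export
setMethod("spectralCounts", "ProteinSet", function(x) x@spectra)

setMethod("show", "ProteinSet", function(object) {
  cat(sprintf("ProteinSet: %d protein(s) x %d run(s)\n",
              nrow(object@info), ncol(object@spectra)))
  cat(sprintf("  probability range: [%.3g, %.3g]; unique peptides: %d-%d\n",
              min(object@info$probability), max(object@info$probability),
              min(object@info$unique_peptides), max(object@info$unique_peptides)))
})

setMethod("length", "ProteinSet", function(x) nrow(x@info))

#' Filter proteins on evidence thresholds
#'
#' Retains proteins with at least \code{minUnique} unique peptides (pooled
#' across all runs) and posterior probability at least \code{minProbability}.
#' The defaults (2 unique peptides, probability 0.93) encode the common
#' practice of pairing a two-peptide rule with the ProteinProphet probability
#' that corresponds to a 1\% protein FDR in the combined analysis; the
#' probability is consumed here, not estimated.
#'
#' @param x a [ProteinSet-class].
#' @param minUnique nonnegative integer.
#' @param minProbability probability threshold in [0, 1].
#' @return a [ProteinSet-class] with the retained records, input order
#'   preserved; the input is untouched.
#' @export
filterProteins <- function(x, minUnique = 2, minProbability = 0.93) {
  stopifnot(is(x, "ProteinSet"))
  if (minUnique < 0) stop("'minUnique' must be >= 0")
  if (minProbability < 0 || minProbability > 1)
    stop("'minProbability' must lie in [0, 1]")
  keep <- x@info$unique_peptides >= minUnique &
    x@info$probability >= minProbability
  ProteinSet(x@info[keep, , drop = FALSE], x@spectra[keep, , drop = FALSE])
}

#' Spectral counts of a ProteinSet as a protein-level CountTable
#'
#' @param x a [ProteinSet-class].
#' @param sampleData optional run metadata (see [readSampleMeta()]).
#' @return a metaproteome [CountTable-class] with \code{featureKind}
#'   \code{"protein"}.
#' @export
proteinCountTable <- function(x, sampleData = NULL) {
  CountTable(x@spectra, layer = "metaproteome", featureKind = "protein",
             sampleData = sampleData)
}
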