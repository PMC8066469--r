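#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.LAYERS <- c("metagenome", "metaproteome")
.FEATURE_KINDS <- c("taxon", "go_term", "protein")

#' CountTable: a feature x sample count matrix for one omics layer
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding nonnegative
#' counts (sequencing reads or peptide spectral matches, PSMs) for one omics
#' layer, tagged with the kind of feature in its rows. Raw counts are
#' integers; real values are permitted because technical-replicate averaging
#' and library normalization produce non-integer tables.
#'
#' @slot layer one of \code{"metagenome"} or \code{"metaproteome"}.
#' @slot featureKind one of \code{"taxon"}, \code{"go_term"}, \code{"protein"}.
#'
#' @seealso [CountTable()] for construction, [readCountTable()] for file input.
#' @name CountTable-class
#' @aliases CountTable-class
#' @exportClass CountTable
setClass("CountTable",
  contains = "SummarizedExperiment",
  slots = c(layer = "character", featureKind = "character")
)

setValidity("CountTable", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msg <- c(msg, sprintf("'layer' must be one of: %s",
                          paste(.LAYERS, collapse = ", ")))
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% .FEATURE_KINDS)
    msg <- c(msg, sprintf("'featureKind' must be one of: %s",
                          paste(.FEATURE_KINDS, collapse = ", ")))
  m <- assay(object)
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "feature and sample names are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicated feature ids: %s",
                          paste(unique(rownames(object)[duplicated(rownames(object))]),
                                collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicated sample ids: %s",
                          paste(unique(colnames(object)[duplicated(colnames(object))]),
                                collapse = ", ")))
  if (any(!is.finite(m)))
    msg <- c(msg, "counts must be finite")
  else if (any(m < 0))
    msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ProteinSet: inferred proteins with per-run spectral counts
#'
#' Holds one row per inferred protein (id, length in amino acids,
#' ProteinProphet-style posterior probability, number of unique peptides
#' pooled over all runs) together with a protein x run matrix of spectral
#' counts. Probabilities are scored upstream; this container only stores and
#' filters them.
#'
#' @slot info data.frame with columns \code{protein_id}, \code{length},
#'   \code{probability}, \code{unique_peptides}.
#' @slot spectra numeric matrix, proteins x runs, nonnegative.
#'
#' @name ProteinSet-class
#' @aliases ProteinSet-class
#' @exportClass ProteinSet
setClass("ProteinSet",
  slots = c(info = "data.frame", spectra = "matrix")
)

setValidity("ProteinSet", function(object) {
  msg <- character()
  need <- c("protein_id", "length", "probability", "unique_peptides")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    info <- object@info
    if (anyDuplicated(info$protein_id))
      msg <- c(msg, sprintf("duplicated protein ids: %s",
        paste(unique(info$protein_id[duplicated(info$protein_id)]), collapse = ", ")))
    if (any(info$length < 1))
      msg <- c(msg, "protein lengths must be >= 1")
    if (any(info$probability < 0 | info$probability > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(info$unique_peptides < 0))
      msg <- c(msg, "unique peptide counts must be nonnegative")
    if (nrow(object@spectra) != nrow(info) ||
        (nrow(info) > 0 && !identical(rownames(object@spectra),
                                      info$protein_id)))
      msg <- c(msg, "spectra rownames must equal info$protein_id")
  }
  if (any(object@spectra < 0)) msg <- c(msg, "spectral counts must be nonnegative")
  if (is.null(colnames(object@spectra)))
    msg <- c(msg, "spectra must have run ids as colnames")
  if (length(msg)) msg else TRUE
})

#' AnnotationMap: protein-level taxonomic and functional annotation
#'
#' Maps protein ids to a taxonomic lineage (ordered ranks, least to most
#' specific, possibly truncated), to a set of GO terms, and optionally to a
#' length in amino acids. Proteins missing a mapping are kept and flagged as
#' unannotated rather than dropped, because unassigned mass matters for
#' mass-conservation and presence/absence analyses.
#'
#' @slot lineages named list; each element a character vector of ranks.
#' @slot goTerms named list; each element a character vector of GO ids.
#' @slot lengths named numeric of amino-acid lengths (possibly empty).
#'
#' @name AnnotationMap-class
#' @aliases AnnotationMap-class
#' @exportClass AnnotationMap
setClass("AnnotationMap",
  slots = c(lineages = "list", goTerms = "list", lengths = "numeric")
)

setValidity("AnnotationMap", function(object) {
  msg <- character()
  if (length(object@lineages) && is.null(names(object@lineages)))
    msg <- c(msg, "lineages must be named by protein id")
  if (length(object@goTerms) && is.null(names(object@goTerms)))
    msg <- c(msg, "goTerms must be named by protein id")
  if (length(object@lengths)) {
    if (is.null(names(object@lengths)))
      msg <- c(msg, "lengths must be named by protein id")
    if (any(object@lengths <= 0))
      msg <- c(msg, "lengths must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' AnosimResult: analysis-of-similarity permutation test result
#'
#' @slot statistic observed ANOSIM R, in [-1, 1].
#' @slot pValue permutation p-value.
#' @slot nPerm number of permutations used (excluding the observed labelling
#'   for Monte-Carlo sampling; total enumerated labellings when exhaustive).
#' @slot exhaustive TRUE when all distinct labellings were enumerated.
#' @slot grouping label describing the grouping factor tested.
#' @slot permStats the permutation null distribution of R.
#'
#' @name AnosimResult-class
#' @aliases AnosimResult-class
#' @exportClass AnosimResult
setClass("AnosimResult",
  slots = c(statistic = "numeric", pValue = "numeric", nPerm = "integer",
            exhaustive = "logical", grouping = "character",
            permStats = "numeric")
)

setValidity("AnosimResult", function(object) {
  msg <- character()
  if (abs(object@statistic) > 1 + 1e-12)
    msg <- c(msg, "R statistic must lie in [-1, 1]")
  if (object@pValue <= 0 || object@pValue > 1)
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' NmdsResult: non-metric multidimensional scaling ordination
#'
#' @slot points sample x dimension coordinate matrix, centred at the origin
#'   and rotated to principal axes.
#' @slot stress final Kruskal stress-1.
#' @slot nIter iterations used by the best restart.
#' @slot converged TRUE when the best restart converged.
#' @slot seed the seed that produced the best restart.
#'
#' @name NmdsResult-class
#' @aliases NmdsResult-class
#' @exportClass NmdsResult
setClass("NmdsResult",
  slots = c(points = "matrix", stress = "numeric", nIter = "integer",
            converged = "logical", seed = "integer")
)

#' SimulationConfig: design of a coupled synthetic dataset
#'
#' Encodes the full experimental design the generator emulates: per-taxon
#' proportion trajectories over (day, treatment) conditions, per-taxon
#' activity multipliers that distort the PSM layer relative to the read
#' layer, layer-specific taxon dropout, library sizes, tank/replicate
#' structure and the protein complement of each taxon.
#'
#' @slot taxa data.frame with columns \code{taxon}, \code{lineage}
#'   (semicolon-delimited ranks, Kingdom to Class, possibly truncated).
#' @slot p taxa x condition matrix of read-layer proportions; columns sum to 1.
#' @slot multipliers named positive numeric; 1 = concordant layers.
#' @slot dropoutProteome,dropoutGenome taxa forced structurally absent from
#'   one layer.
#' @slot days ordered experimental days.
#' @slot treatments treatment labels.
#' @slot tanksPerTreatment,techReps metaproteome replication structure.
#' @slot nReads,nPsm library sizes (reads per metagenome library, PSMs per
#'   mass-spectrometry run).
#' @slot proteins data.frame describing each taxon's proteins: id, taxon,
#'   length, within-taxon expression share, simulated evidence scores.
#' @slot goAssign named list mapping protein id to GO term ids.
#' @slot seed integer seed the design was drawn with.
#'
#' @name SimulationConfig-class
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(taxa = "data.frame", p = "matrix", multipliers = "numeric",
            dropoutProteome = "character", dropoutGenome = "character",
            days = "numeric", treatments = "character",
            tanksPerTreatment = "integer", techReps = "integer",
            nReads = "numeric", nPsm = "numeric",
            proteins = "data.frame", goAssign = "list", seed = "integer")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!all(c("taxon", "lineage") %in% names(object@taxa)))
    msg <- c(msg, "taxa must have columns taxon, lineage")
  if (nrow(object@p) != nrow(object@taxa))
    msg <- c(msg, "p must have one row per taxon")
  cs <- colSums(object@p)
  if (any(abs(cs - 1) > 1e-8))
    msg <- c(msg, "proportion columns must sum to 1")
  if (any(object@p < 0)) msg <- c(msg, "proportions must be nonnegative")
  if (any(object@multipliers <= 0))
    msg <- c(msg, "activity multipliers must be positive")
  if (!all(names(object@multipliers) == object@taxa$taxon))
    msg <- c(msg, "multipliers must be named by taxon, in taxa order")
  if (object@nReads < 1 || object@nPsm < 1)
    msg <- c(msg, "library sizes must be >= 1")
  if (object@tanksPerTreatment < 1L || object@techReps < 1L)
    msg <- c(msg, "tanksPerTreatment and techReps must be >= 1")
  bad <- setdiff(c(object@dropoutProteome, object@dropoutGenome),
                 object@taxa$taxon)
  if (length(bad))
    msg <- c(msg, sprintf("dropout taxa not in design: %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: generating proportions behind a synthetic dataset
#'
#' Ground truth for recovery tests: the read-layer proportions p and the
#' activity-distorted PSM-layer proportions q = p * a / sum(p * a) for every
#' (day, treatment) condition, the multiplier vector and the dropout sets.
#'
#' @slot p,q taxa x condition proportion matrices (columns sum to 1).
#' @slot multipliers named positive numeric.
#' @slot dropoutProteome,dropoutGenome structurally absent taxa per layer.
#'
#' @name SimulationTruth-class
#' @aliases SimulationTruth-class
#' @exportClass SimulationTruth
setClass("SimulationTruth",
  slots = c(p = "matrix", q = "matrix", multipliers = "numeric",
            dropoutProteome = "character", dropoutGenome = "character")
)

setValidity("SimulationTruth", function(object) {
  msg <- character()
  if (any(abs(colSums(object@q) - 1) > 1e-8))
    msg <- c(msg, "q columns must sum to 1")
  if (length(msg)) msg else TRUE
})
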