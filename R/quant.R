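#' @include countTable.R proteinSet.R annotationMap.R
NULL

#' Average technical replicates of a metaproteome table
#'
#' Collapses runs sharing a \code{tech_replicate_group} to their arithmetic
#' mean, yielding one column per biological sample. Averaging happens on raw
#' spectral counts, before NSAF and before library normalization: averaging
#' normalized values would weight runs with fewer total PSMs more heavily.
#' The operation is idempotent on already-averaged tables (each group then
#' has a single member run).
#'
#' @param x a [CountTable-class] whose columns are runs.
#' @param meta metadata data.frame covering every run column, with
#'   \code{sample_id} and \code{tech_replicate_group}.
#' @return a [CountTable-class] with one column per replicate group, in
#'   first-appearance order; \code{colData} carries the group's metadata.
#' @export
averageTechnicalReplicates <- function(x, meta) {
  m <- counts(x)
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx))
    stop("run(s) missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  grp <- meta$tech_replicate_group[idx]
  if (any(!nzchar(grp) | is.na(grp)))
    stop("every run needs a nonempty tech_replicate_group")
  groups <- unique(grp)
  out <- vapply(groups, function(g) rowMeans(m[, grp == g, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), groups))
  first <- idx[match(groups, grp)]
  gm <- meta[first, , drop = FALSE]
  gm$sample_id <- groups
  gm$tech_replicate_group <- groups
  CountTable(out, layer = omicsLayer(x), featureKind = featureKind(x),
             sampleData = gm)
}

#' Normalized spectral abundance factors (NSAF)
#'
#' For each sample, NSAF_i = (SpC_i / L_i) / sum_j (SpC_j / L_j): a protein's
#' spectral count divided by its length, normalized to the sample total of
#' length-corrected counts. Length correction removes the advantage longer
#' proteins have in accumulating spectra; each column sums to one.
#'
#' @param x a protein-level [CountTable-class] (typically filtered and
#'   replicate-averaged), or a [ProteinSet-class].
#' @param lengths named numeric of amino-acid lengths covering every protein;
#'   defaults to the lengths stored in a [ProteinSet-class] input.
#' @return a [CountTable-class] of NSAF values; columns sum to 1 (a protein
#'   with zero counts has NSAF 0).
#' @examples
#' m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("P1", "P2"), "s1"))
#' ct <- CountTable(m, "metaproteome", "protein")
#' counts(computeNSAF(ct, c(P1 = 100, P2 = 200)))  # 2/3, 1/3
#' @export
computeNSAF <- function(x, lengths = NULL) {
  if (is(x, "ProteinSet")) {
    if (is.null(lengths))
      lengths <- stats::setNames(proteinInfo(x)$length,
                                 proteinInfo(x)$protein_id)
    x <- proteinCountTable(x)
  }
  stopifnot(is(x, "CountTable"), featureKind(x) == "protein")
  m <- counts(x)
  L <- lengths[rownames(m)]
  if (anyNA(L))
    stop("length missing for protein(s): ",
         paste(rownames(m)[is.na(L)], collapse = ", "))
  if (any(L <= 0)) stop("protein lengths must be positive")
  saf <- m / as.numeric(L)
  tot <- colSums(saf)
  if (any(tot == 0))
    stop("all-zero spectral counts in sample(s): ",
         paste(colnames(m)[tot == 0], collapse = ", "))
  nsaf <- sweep(saf, 2, tot, "/")
  CountTable(nsaf, layer = "metaproteome", featureKind = "protein",
             sampleData = if (ncol(colData(x))) sampleMeta(x) else NULL)
}

.DEFAULT_RANKS <- c("Kingdom", "Phylum", "Class")

#' Aggregate a protein-level table to taxa or GO terms
#'
#' Taxon mode: each protein's counts are added to its lineage entry at the
#' requested rank; when a lineage stops above that rank the protein is
#' counted at its deepest available rank, reproducing mixed
#' Kingdom-through-Class groups. GO mode: each protein's counts are added to
#' every GO term it carries (a PSM may legitimately count toward multiple
#' terms, so term totals are not spectrum totals). Proteins with no mapping
#' accumulate under \code{"unassigned"}; aggregation therefore conserves
#' per-sample mass in taxon mode.
#'
#' @param x a protein-level [CountTable-class].
#' @param ann an [AnnotationMap-class].
#' @param level \code{"taxon"} or \code{"go_term"}.
#' @param rank rank name for taxon mode (one of \code{ranks}).
#' @param ranks the ordered rank vocabulary of the lineage strings.
#' @return an aggregated [CountTable-class] on the same layer.
#' @export
aggregatePSMs <- function(x, ann, level = c("taxon", "go_term"),
                          rank = "Class", ranks = .DEFAULT_RANKS) {
  stopifnot(is(x, "CountTable"), featureKind(x) == "protein")
  level <- match.arg(level)
  m <- counts(x)
  ids <- rownames(m)
  if (level == "taxon") {
    k <- match(rank, ranks)
    if (is.na(k))
      stop("unknown rank '", rank, "'; expected one of: ",
           paste(ranks, collapse = ", "))
    lin <- proteinLineage(ann, ids)
    key <- vapply(lin, function(v) {
      if (!length(v)) "unassigned" else v[min(k, length(v))]
    }, character(1))
    feats <- unique(key)
    out <- rowsum(m, group = factor(key, levels = feats), reorder = FALSE)
    out <- matrix(out, nrow = length(feats),
                  dimnames = list(feats, colnames(m)))
  } else {
    go <- proteinGO(ann, ids)
    nTerms <- lengths(go)
    key <- unlist(go, use.names = FALSE)
    key <- c(key, rep("unassigned", sum(nTerms == 0)))
    rows <- c(rep(seq_along(ids), nTerms), which(nTerms == 0))
    feats <- unique(key)
    out <- rowsum(m[rows, , drop = FALSE],
                  group = factor(key, levels = feats), reorder = FALSE)
    out <- matrix(out, nrow = length(feats),
                  dimnames = list(feats, colnames(m)))
  }
  CountTable(out, layer = omicsLayer(x),
             featureKind = if (level == "taxon") "taxon" else "go_term",
             sampleData = if (ncol(colData(x))) sampleMeta(x) else NULL)
}
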