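#' @include AllClasses.R
NULL

# R statistic from a symmetric rank matrix and a grouping: (mean between-group
# rank - mean within-group rank) / (M/2), M = n(n-1)/2 pairwise dissimilarities.
.anosimStat <- function(rankMat, groups, lower) {
  within <- outer(groups, groups, "==")[lower]
  rk <- rankMat[lower]
  (mean(rk[!within]) - mean(rk[within])) / (length(rk) / 2)
}

.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of whether dissimilarities between groups
#' exceed those within groups. All pairwise dissimilarities are ranked
#' (average ranks for ties) and R = (mean between-group rank - mean
#' within-group rank) / (M/2) with M = n(n-1)/2, so R lies in [-1, 1] and
#' R = 1 means every between-group pair is more dissimilar than every
#' within-group pair. The null distribution permutes group labels; the
#' Monte-Carlo p-value uses the add-one correction
#' p = (1 + #\{permuted R >= observed\}) / (1 + nPerm), so its floor at 999
#' permutations is 0.001. With \code{exhaustive = TRUE} all n! labellings
#' are enumerated and p is the exact fraction with R >= observed.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @param groups grouping vector, >= 2 groups of >= 2 members each.
#' @param nPerm number of Monte-Carlo permutations.
#' @param seed integer seed for reproducible permutations.
#' @param exhaustive enumerate all labellings instead of sampling (n <= 8).
#' @return an [AnosimResult-class].
#' @export
anosim <- function(d, groups, nPerm = 999, seed = 1L, exhaustive = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) ||
      !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("'d' must be a square symmetric dissimilarity matrix")
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) stop("'groups' must label every sample")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members, got size 1: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "))
  lower <- lower.tri(d)
  rankMat <- matrix(0, n, n)
  rankMat[lower] <- rank(d[lower])  # average ranks on ties
  obs <- .anosimStat(rankMat, groups, lower)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8 samples")
    perms <- .allPermutations(n)
    stats <- apply(perms, 1, function(ix)
      .anosimStat(rankMat, groups[ix], lower))
    p <- mean(stats >= obs - 1e-12)
    nP <- nrow(perms)
  } else {
    stats <- withr::with_seed(seed, vapply(seq_len(nPerm), function(i)
      .anosimStat(rankMat, sample(groups), lower), numeric(1)))
    p <- (1 + sum(stats >= obs - 1e-12)) / (1 + nPerm)
    nP <- as.integer(nPerm)
  }
  new("AnosimResult", statistic = obs, pValue = p, nPerm = nP,
      exhaustive = exhaustive, grouping = "groups", permStats = stats)
}

setMethod("show", "AnosimResult", function(object) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutation%s)\n",
              object@statistic, object@pValue,
              if (object@exhaustive) "exhaustive" else "Monte-Carlo",
              object@nPerm, if (object@nPerm == 1L) "" else "s"))
})

#' @rdname anosim
#' @param object an [AnosimResult-class].
#' @export
anosimR <- function(object) object@statistic

#' @rdname anosim
#' @export
anosimP <- function(object) object@pValue
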