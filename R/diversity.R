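#' @include countTable.R
NULL

#' Shannon-Weaver diversity index
#'
#' H = -sum p_i log(p_i) over the nonzero proportions p_i = c_i / sum(c).
#' Natural-log units by default (the convention under which a community of a
#' few hundred taxa sits around H = 5); the base is configurable. Invariant
#' to rescaling all counts by a positive constant.
#'
#' @param counts nonnegative numeric vector with at least one positive entry.
#' @param base logarithm base.
#' @return H >= 0 (0 for a single-feature community).
#' @export
shannonWeaver <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Simpson reciprocal diversity index
#'
#' 1/D = 1 / sum(p_i^2); ranges from 1 (single feature) to k (uniform over k
#' features). Invariant to rescaling all counts by a positive constant.
#'
#' @param counts nonnegative numeric vector with at least one positive entry.
#' @return value in [1, k].
#' @export
simpsonReciprocal <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero")
  p <- counts / tot
  1 / sum(p^2)
}

#' Per-sample diversity indices of a count table
#'
#' @param x a [CountTable-class].
#' @param base logarithm base for Shannon-Weaver.
#' @return data.frame: \code{sample_id}, \code{shannon_weaver},
#'   \code{simpson_reciprocal}.
#' @export
diversityTable <- function(x, base = exp(1)) {
  m <- counts(x)
  data.frame(
    sample_id = colnames(m),
    shannon_weaver = apply(m, 2, shannonWeaver, base = base),
    simpson_reciprocal = apply(m, 2, simpsonReciprocal),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) between sample columns;
#' 0 for identical profiles, 1 for disjoint supports, symmetric, invariant
#' to feature order.
#'
#' @param x a [CountTable-class] or a nonnegative feature x sample matrix
#'   with at least 2 samples.
#' @return symmetric sample x sample dissimilarity matrix with zero diagonal.
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "CountTable")) counts(x) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (any(m < 0)) stop("counts must be nonnegative")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(m[, i] + m[, j])
    if (denom == 0)
      stop("Bray-Curtis undefined for all-zero sample pair: ",
           colnames(m)[i], ", ", colnames(m)[j])
    d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
  }
  d
}
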