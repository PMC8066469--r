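#' @include AllClasses.R
NULL

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Embeds samples in k dimensions so that the rank order of embedded
#' distances matches the rank order of the input dissimilarities, minimizing
#' Kruskal stress-1 by iterative monotone regression (engine:
#' \code{vegan::monoMDS}, model \code{"global"}). Because the criterion has
#' local minima, the fit is restarted from a metric-scaling start plus
#' \code{nRestarts - 1} seed-derived random starts and the lowest-stress
#' solution is kept; the result is centred at the origin and rotated to
#' principal axes with a fixed sign convention, so a given seed always
#' yields the same orientation. Samples at zero dissimilarity are embedded
#' at coincident coordinates (they are collapsed before fitting and expanded
#' afterwards). Non-convergence is reported in the result, not raised.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @param k number of dimensions, < number of distinct samples.
#' @param seed integer seed.
#' @param nRestarts number of starts (first is metric scaling).
#' @param maxIter maximum iterations per start.
#' @param tol minimum stress treated as zero (convergence criterion).
#' @return an [NmdsResult-class].
#' @export
nmds <- function(d, k = 2, seed = 1L, nRestarts = 20, maxIter = 200,
                 tol = 1e-6) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) ||
      !isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop("'d' must be a square symmetric dissimilarity matrix")
  n <- nrow(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("s", seq_len(n))
  # collapse zero-dissimilarity duplicates (connected components of d == 0)
  rep_of <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(i - 1L))
    if (d[i, j] <= 0) rep_of[i] <- rep_of[j]
  reps <- unique(rep_of)
  if (k >= length(reps))
    stop("'k' must be smaller than the number of distinct samples")
  dd <- stats::as.dist(d[reps, reps, drop = FALSE])
  fitOne <- function(init, s) {
    res <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                          maxit = maxIter, smin = tol)
    # icause 1 = iteration cap hit; 2-4 = a convergence criterion fired
    list(points = res$points, stress = res$stress, iters = res$iters,
         converged = res$icause != 1L, seed = s)
  }
  # first start: classical (metric) scaling, deterministic
  metric <- suppressWarnings(stats::cmdscale(dd, k = k))
  if (ncol(metric) < k)
    metric <- cbind(metric, matrix(0, nrow(metric), k - ncol(metric)))
  best <- fitOne(metric, as.integer(seed))
  if (nRestarts > 1) {
    for (i in seq_len(nRestarts - 1)) {
      s <- as.integer(seed) + i
      init <- withr::with_seed(s, matrix(stats::rnorm(length(reps) * k),
                                         ncol = k))
      cand <- fitOne(init, s)
      if (cand$stress < best$stress - 1e-12) best <- cand
    }
  }
  pts <- best$points
  pts <- sweep(pts, 2, colMeans(pts))
  if (nrow(pts) > 1) {
    pc <- stats::prcomp(pts, center = FALSE)
    pts <- pc$x[, seq_len(k), drop = FALSE]
  }
  for (j in seq_len(ncol(pts))) {        # deterministic axis orientation
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  full <- pts[match(rep_of, reps), , drop = FALSE]
  dimnames(full) <- list(rownames(d), paste0("NMDS", seq_len(k)))
  new("NmdsResult", points = full, stress = best$stress,
      nIter = as.integer(best$iters), converged = isTRUE(best$converged),
      seed = best$seed)
}

setMethod("show", "NmdsResult", function(object) {
  cat(sprintf("NMDS: %d sample(s) in %d dimension(s); stress = %.4g; %s (%d iterations)\n",
              nrow(object@points), ncol(object@points), object@stress,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
})

#' @rdname nmds
#' @param object an [NmdsResult-class].
#' @export
nmdsPoints <- function(object) object@points

#' @rdname nmds
#' @export
nmdsStress <- function(object) object@stress
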