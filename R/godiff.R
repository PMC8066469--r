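#' @include concordance.R
NULL

#' Pool a condition's samples into one count vector
#'
#' Arithmetic mean, per feature, over the samples matching a (day, treatment)
#' condition (after technical-replicate averaging upstream), so each
#' condition is represented by a single pooled profile.
#'
#' @param x a [CountTable-class] with day/treatment in \code{colData} (or
#'   supply \code{meta}).
#' @param day,treatment the condition.
#' @param meta optional metadata data.frame overriding \code{colData}.
#' @return named numeric vector of pooled per-feature counts.
#' @export
poolCondition <- function(x, day, treatment, meta = sampleMeta(x)) {
  m <- counts(x)
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  sel <- meta$day[idx] == day & meta$treatment[idx] == treatment
  if (!any(sel))
    stop(sprintf("no samples match day %s, treatment %s", day, treatment))
  rowMeans(m[, sel, drop = FALSE])
}

#' Laplace-smoothed log ratio and two-proportion test for one GO term
#'
#' Compares a term's share of PSMs between two conditions. The effect size
#' is log2(((psmB + pseudo) / (totalB + pseudo)) /
#' ((psmA + pseudo) / (totalA + pseudo))) with an additive (Laplace)
#' pseudocount, so terms absent from one condition remain comparable. The
#' p-value is a two-sided two-proportion z-test on the smoothed proportions
#' with the pooled-variance estimate. Swapping the conditions negates the
#' log ratio.
#'
#' @param psmA,totalA term PSMs and library total in condition A.
#' @param psmB,totalB same for condition B.
#' @param pseudo positive pseudocount (default 1, Laplace).
#' @return list with \code{log2Ratio} and \code{pValue}.
#' @export
goRatioTest <- function(psmA, totalA, psmB, totalB, pseudo = 1) {
  if (pseudo <= 0) stop("'pseudo' must be positive")
  if (totalA <= 0 || totalB <= 0) stop("library totals must be positive")
  if (psmA < 0 || psmB < 0 || psmA > totalA || psmB > totalB)
    stop("need 0 <= psm <= total in both conditions")
  pA <- (psmA + pseudo) / (totalA + pseudo)
  pB <- (psmB + pseudo) / (totalB + pseudo)
  log2Ratio <- log2(pB) - log2(pA)
  nA <- totalA + pseudo; nB <- totalB + pseudo
  pPool <- (psmA + psmB + 2 * pseudo) / (nA + nB)
  se <- sqrt(pPool * (1 - pPool) * (1 / nA + 1 / nB))
  z <- if (se == 0) 0 else (pB - pA) / se
  list(log2Ratio = log2Ratio,
       pValue = max(min(2 * stats::pnorm(-abs(z)), 1), .Machine$double.xmin))
}

#' Benjamini-Hochberg q-values
#'
#' Monotone step-up false-discovery-rate adjustment; q >= p elementwise and
#' input order is preserved.
#'
#' @param p p-values in (0, 1].
#' @return numeric vector of q-values, same order as \code{p}.
#' @export
correctQvalues <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise differential GO-term analysis
#'
#' For every consecutive-day pair within each treatment and every
#' between-treatment pair within each day, pools each condition's samples
#' ([poolCondition()]), tests every GO term with [goRatioTest()] against the
#' condition's library total, applies [correctQvalues()] within the
#' comparison, and flags terms with q <= alpha.
#'
#' @param x a GO-term [CountTable-class] (metaproteome PSMs), replicate-
#'   averaged, with day/treatment in \code{colData}.
#' @param alpha significance level on the q-value.
#' @param pseudo Laplace pseudocount.
#' @param dayOrder ordered experimental days.
#' @return data.frame with one row per (comparison, term): condition labels,
#'   pooled counts and totals, \code{log2_ratio}, \code{p_value},
#'   \code{q_value}, \code{significant}.
#' @export
pairwiseGoTests <- function(x, alpha = 0.05, pseudo = 1,
                            dayOrder = c(1, 5, 8, 12)) {
  meta <- sampleMeta(x)
  conds <- unique(data.frame(day = meta$day, treatment = meta$treatment,
                             stringsAsFactors = FALSE))
  pairs <- list()
  for (trt in unique(conds$treatment)) {
    days <- intersect(dayOrder, conds$day[conds$treatment == trt])
    if (length(days) > 1)
      for (i in seq_len(length(days) - 1))
        pairs[[length(pairs) + 1L]] <-
          list(a = c(days[i], trt), b = c(days[i + 1], trt))
  }
  for (dy in intersect(dayOrder, conds$day)) {
    trts <- sort(unique(conds$treatment[conds$day == dy]))
    if (length(trts) > 1)
      for (i in seq_len(length(trts) - 1)) for (j in (i + 1):length(trts))
        pairs[[length(pairs) + 1L]] <-
          list(a = c(dy, trts[i]), b = c(dy, trts[j]))
  }
  if (!length(pairs)) stop("no pairwise comparisons in the design")
  out <- lapply(pairs, function(pr) {
    a <- poolCondition(x, as.numeric(pr$a[1]), pr$a[2])
    b <- poolCondition(x, as.numeric(pr$b[1]), pr$b[2])
    totA <- sum(a); totB <- sum(b)
    tests <- lapply(seq_along(a), function(i)
      goRatioTest(a[i], totA, b[i], totB, pseudo = pseudo))
    p <- vapply(tests, `[[`, numeric(1), "pValue")
    q <- correctQvalues(p)
    data.frame(
      go_term = names(a),
      condition_a = .conditionKey(as.numeric(pr$a[1]), pr$a[2]),
      condition_b = .conditionKey(as.numeric(pr$b[1]), pr$b[2]),
      psm_a = unname(a), psm_b = unname(b),
      total_a = totA, total_b = totB,
      log2_ratio = vapply(tests, `[[`, numeric(1), "log2Ratio"),
      p_value = p, q_value = q, significant = q <= alpha,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-taxon contributions to one GO term's PSMs
#'
#' Splits the pooled PSMs of a GO term in one (day, treatment) condition by
#' the taxonomic origin of the contributing proteins, at the mixed
#' Kingdom-through-Class convention of [aggregatePSMs()]. Shares sum to 1.
#'
#' @param x a protein-level [CountTable-class] with day/treatment in
#'   \code{colData}.
#' @param ann an [AnnotationMap-class].
#' @param goTerm GO term id.
#' @param day,treatment the condition.
#' @param rank,ranks taxonomic reporting convention (see [aggregatePSMs()]).
#' @return data.frame: \code{go_term}, \code{day}, \code{treatment},
#'   \code{taxon}, \code{psm}, \code{fraction}.
#' @export
taxonContributions <- function(x, ann, goTerm, day, treatment,
                               rank = "Class", ranks = .DEFAULT_RANKS) {
  stopifnot(is(x, "CountTable"), featureKind(x) == "protein")
  pooled <- poolCondition(x, day, treatment)
  go <- proteinGO(ann, names(pooled))
  carry <- vapply(go, function(v) goTerm %in% v, logical(1))
  pooled <- pooled[carry]
  if (!length(pooled) || sum(pooled) <= 0)
    stop(sprintf("GO term %s has no attributed PSMs at day %s, %s",
                 goTerm, day, treatment))
  k <- match(rank, ranks)
  if (is.na(k)) stop("unknown rank '", rank, "'")
  lin <- proteinLineage(ann, names(pooled))
  taxon <- vapply(lin, function(v)
    if (!length(v)) "unassigned" else v[min(k, length(v))], character(1))
  psm <- tapply(pooled, taxon, sum)
  data.frame(go_term = goTerm, day = day, treatment = treatment,
             taxon = names(psm), psm = as.numeric(psm),
             fraction = as.numeric(psm) / sum(psm),
             row.names = NULL, stringsAsFactors = FALSE)
}
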