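#' @include quant.R
NULL

.conditionKey <- function(day, treatment) sprintf("d%g_%s", day, treatment)

#' Library-normalize a count table
#'
#' Divides each sample column by its own total, so entries become the ratio
#' of reads (or PSMs) for a feature to all reads (PSMs) in that library/run.
#'
#' @param x a [CountTable-class] with positive column totals.
#' @return a [CountTable-class] of ratios; columns sum to 1.
#' @export
normalizeLibrary <- function(x) {
  m <- counts(x)
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("all-zero library: ", paste(colnames(m)[tot <= 0], collapse = ", "))
  CountTable(sweep(m, 2, tot, "/"), layer = omicsLayer(x),
             featureKind = featureKind(x),
             sampleData = if (ncol(colData(x))) sampleMeta(x) else NULL)
}

#' Per-condition relative abundances
#'
#' Library-normalizes a table and averages the resulting ratios over the
#' samples belonging to each (day, treatment) condition, producing one
#' relative-abundance value per feature per condition.
#'
#' @param x a [CountTable-class].
#' @param meta metadata with \code{sample_id}, \code{day}, \code{treatment}
#'   covering every column; defaults to the table's own \code{colData}.
#' @return data.frame with columns \code{feature_id}, \code{day},
#'   \code{treatment}, \code{ratio}.
#' @export
conditionRatios <- function(x, meta = sampleMeta(x)) {
  if (!all(c("sample_id", "day", "treatment") %in% names(meta)))
    stop("metadata must provide sample_id, day and treatment")
  r <- counts(normalizeLibrary(x))
  idx <- match(colnames(r), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(r)[is.na(idx)], collapse = ", "))
  day <- meta$day[idx]; trt <- meta$treatment[idx]
  key <- .conditionKey(day, trt)
  keys <- unique(key)
  avg <- vapply(keys, function(k) rowMeans(r[, key == k, drop = FALSE]),
                numeric(nrow(r)))
  avg <- matrix(avg, nrow = nrow(r), dimnames = list(rownames(r), keys))
  first <- match(keys, key)
  data.frame(
    feature_id = rep(rownames(avg), times = length(keys)),
    day = rep(day[first], each = nrow(avg)),
    treatment = rep(trt[first], each = nrow(avg)),
    ratio = as.numeric(avg),
    stringsAsFactors = FALSE)
}

#' First-zeroed temporal deltas of relative abundances
#'
#' For each (feature, treatment) series ordered by \code{dayOrder}, the first
#' observed time point is set to 0 and each subsequent delta is
#' ratio[n] - ratio[n - 1] over consecutive observed days. A feature
#' unobserved at a day a treatment was sampled on gets ratio 0 there
#' (absence is informative in count data). The deltas telescope:
#' their sum equals ratio[last] - ratio[first].
#'
#' @param series data.frame from [conditionRatios()] (columns
#'   \code{feature_id}, \code{day}, \code{treatment}, \code{ratio}).
#' @param dayOrder ordered vector of experimental days; days of the series
#'   must belong to it.
#' @return the series completed over observed days, with a \code{delta}
#'   column, ordered by treatment, feature and day.
#' @export
temporalDeltas <- function(series, dayOrder = c(1, 5, 8, 12)) {
  stopifnot(all(c("feature_id", "day", "treatment", "ratio") %in%
                  names(series)))
  bad <- setdiff(unique(series$day), dayOrder)
  if (length(bad))
    stop("day(s) not in dayOrder: ", paste(bad, collapse = ", "))
  out <- lapply(split(series, series$treatment), function(ss) {
    days <- intersect(dayOrder, unique(ss$day))
    feats <- unique(ss$feature_id)
    dup <- duplicated(ss[c("feature_id", "day")])
    if (any(dup))
      stop("duplicate day in series for feature(s): ",
           paste(unique(ss$feature_id[dup]), collapse = ", "))
    full <- expand.grid(feature_id = feats, day = days,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    full$treatment <- ss$treatment[1]
    m <- match(paste(full$feature_id, full$day),
               paste(ss$feature_id, ss$day))
    full$ratio <- ifelse(is.na(m), 0, ss$ratio[m])
    full <- full[order(match(full$feature_id, feats),
                       match(full$day, days)), ]
    full$delta <- stats::ave(full$ratio, full$feature_id,
                             FUN = function(r) c(0, diff(r)))
    full
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[c("feature_id", "treatment", "day", "ratio", "delta")]
}

#' Read-versus-PSM concordance regression
#'
#' Ordinary least squares of metaproteome values (y) on metagenome values
#' (x), paired by feature for one (day, treatment): how well do PSMs
#' correspond to reads? R-squared is 1 - SS_res/SS_tot; a constant response
#' (SS_tot = 0) is reported as 0, since a flat PSM profile carries no
#' variance a varying read profile could explain.
#'
#' @param readValues,psmValues numeric vectors of per-feature values; when
#'   both are named, names must agree as sets and pairing is by name.
#' @return list with \code{slope}, \code{intercept}, \code{rSquared},
#'   \code{nFeatures}.
#' @export
pairedConcordance <- function(readValues, psmValues) {
  if (!is.null(names(readValues)) && !is.null(names(psmValues))) {
    diffs <- c(setdiff(names(readValues), names(psmValues)),
               setdiff(names(psmValues), names(readValues)))
    if (length(diffs))
      stop("mismatched feature sets: ", paste(unique(diffs), collapse = ", "))
    psmValues <- psmValues[names(readValues)]
  } else if (length(readValues) != length(psmValues)) {
    stop("readValues and psmValues must have equal length")
  }
  n <- length(readValues)
  if (n < 2) stop("need at least 2 paired features for a fit")
  fit <- stats::lm(y ~ x, data = data.frame(x = readValues, y = psmValues))
  ssTot <- sum((psmValues - mean(psmValues))^2)
  ssRes <- sum(stats::residuals(fit)^2)
  r2 <- if (ssTot == 0) 0 else 1 - ssRes / ssTot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = max(0, min(1, r2)),
       nFeatures = n)
}

#' Concordance regressions for every (day, treatment) condition
#'
#' Computes per-condition relative abundances in both layers, zero-fills
#' features missing from one layer, and fits [pairedConcordance()] for each
#' condition shared by the two designs. With \code{on = "delta"} the
#' regression uses first-zeroed temporal deltas instead of the ratios.
#'
#' @param metagenome,metaproteome [CountTable-class] objects aggregated at
#'   the same feature kind, with day/treatment in their \code{colData}.
#' @param on regress \code{"ratio"} (default, the literal reading of the
#'   plotted quantities) or \code{"delta"}.
#' @param dayOrder ordered experimental days (used for deltas).
#' @return data.frame with one row per condition: \code{day},
#'   \code{treatment}, \code{feature_kind}, \code{n_features}, \code{slope},
#'   \code{intercept}, \code{r_squared}.
#' @export
concordanceByCondition <- function(metagenome, metaproteome,
                                   on = c("ratio", "delta"),
                                   dayOrder = c(1, 5, 8, 12)) {
  on <- match.arg(on)
  stopifnot(featureKind(metagenome) == featureKind(metaproteome))
  value <- function(x) {
    s <- conditionRatios(x)
    if (on == "delta") {
      s <- temporalDeltas(s, dayOrder = dayOrder)
      s$value <- s$delta
    } else s$value <- s$ratio
    s
  }
  mg <- value(metagenome); mp <- value(metaproteome)
  keys <- intersect(unique(.conditionKey(mg$day, mg$treatment)),
                    unique(.conditionKey(mp$day, mp$treatment)))
  if (!length(keys)) stop("no overlapping (day, treatment) conditions")
  feats <- union(unique(mg$feature_id), unique(mp$feature_id))
  rows <- lapply(keys, function(k) {
    a <- mg[.conditionKey(mg$day, mg$treatment) == k, ]
    b <- mp[.conditionKey(mp$day, mp$treatment) == k, ]
    x <- stats::setNames(rep(0, length(feats)), feats)
    y <- x
    x[a$feature_id] <- a$value
    y[b$feature_id] <- b$value
    fit <- pairedConcordance(x, y)
    data.frame(day = a$day[1], treatment = a$treatment[1],
               feature_kind = featureKind(metagenome),
               n_features = fit$nFeatures, slope = fit$slope,
               intercept = fit$intercept, r_squared = fit$rSquared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$treatment, out$day), ]
}

#' Activity bias of a taxon: PSM share versus read share
#'
#' log2((psmRatio + pseudo) / (readRatio + pseudo)). Positive values mean a
#' taxon contributes more PSMs than its read share predicts (more
#' metabolically active than presence alone suggests); negative values the
#' converse; exactly equal ratios give exactly 0. The pseudocount keeps the
#' ratio defined when a taxon is absent from one layer.
#'
#' @param readRatio,psmRatio relative abundances in [0, 1] (vectorized).
#' @param pseudo positive smoothing constant.
#' @return numeric vector of log2 bias values.
#' @export
activityBias <- function(readRatio, psmRatio, pseudo = 1e-6) {
  if (pseudo <= 0) stop("'pseudo' must be positive")
  if (any(readRatio < 0 | readRatio > 1) || any(psmRatio < 0 | psmRatio > 1))
    stop("ratios must lie in [0, 1]")
  out <- log2((psmRatio + pseudo) / (readRatio + pseudo))
  out[psmRatio == readRatio] <- 0
  out
}

#' Per-taxon activity bias for every shared condition
#'
#' @param metagenome,metaproteome taxon-level [CountTable-class] objects with
#'   day/treatment in \code{colData}.
#' @param pseudo smoothing constant for [activityBias()].
#' @return data.frame: \code{feature_id}, \code{day}, \code{treatment},
#'   \code{read_ratio}, \code{psm_ratio}, \code{log2_bias}.
#' @export
activityBiasTable <- function(metagenome, metaproteome, pseudo = 1e-6) {
  mg <- conditionRatios(metagenome)
  mp <- conditionRatios(metaproteome)
  keys <- intersect(unique(.conditionKey(mg$day, mg$treatment)),
                    unique(.conditionKey(mp$day, mp$treatment)))
  if (!length(keys)) stop("no overlapping (day, treatment) conditions")
  feats <- union(unique(mg$feature_id), unique(mp$feature_id))
  rows <- lapply(keys, function(k) {
    a <- mg[.conditionKey(mg$day, mg$treatment) == k, ]
    b <- mp[.conditionKey(mp$day, mp$treatment) == k, ]
    x <- stats::setNames(rep(0, length(feats)), feats)
    y <- x
    x[a$feature_id] <- a$ratio
    y[b$feature_id] <- b$ratio
    data.frame(feature_id = feats, day = a$day[1], treatment = a$treatment[1],
               read_ratio = unname(x), psm_ratio = unname(y),
               log2_bias = activityBias(unname(x), unname(y), pseudo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-layer presence/absence classification
#'
#' Pools counts within each (day, treatment) condition per layer and labels
#' every feature as detected in \code{both} layers, \code{metagenome_only}
#' (present but not metabolically active at the proteome's detection level),
#' \code{metaproteome_only}, or \code{neither}. Features absent from one
#' table's feature list count as 0 there.
#'
#' @param metagenome,metaproteome [CountTable-class] objects aggregated at
#'   the same level, with day/treatment in \code{colData}.
#' @return data.frame: \code{feature_id}, \code{day}, \code{treatment},
#'   \code{read_count}, \code{psm_count}, \code{status}.
#' @export
crossLayerPresence <- function(metagenome, metaproteome) {
  pool <- function(x) {
    meta <- sampleMeta(x)
    m <- counts(x)
    key <- .conditionKey(meta$day, meta$treatment)
    keys <- unique(key)
    out <- vapply(keys, function(k) rowSums(m[, key == k, drop = FALSE]),
                  numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), keys))
    list(m = out, day = meta$day[match(keys, key)],
         trt = meta$treatment[match(keys, key)])
  }
  a <- pool(metagenome); b <- pool(metaproteome)
  keys <- intersect(colnames(a$m), colnames(b$m))
  if (!length(keys)) stop("no overlapping (day, treatment) conditions")
  feats <- union(rownames(a$m), rownames(b$m))
  rows <- lapply(keys, function(k) {
    x <- stats::setNames(rep(0, length(feats)), feats)
    y <- x
    x[rownames(a$m)] <- a$m[, k]
    y[rownames(b$m)] <- b$m[, k]
    status <- ifelse(x > 0 & y > 0, "both",
              ifelse(x > 0, "metagenome_only",
              ifelse(y > 0, "metaproteome_only", "neither")))
    i <- match(k, colnames(a$m))
    data.frame(feature_id = feats, day = a$day[i], treatment = a$trt[i],
               read_count = unname(x), psm_count = unname(y),
               status = unname(status), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
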