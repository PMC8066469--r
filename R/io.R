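#' @include countTable.R proteinSet.R annotationMap.R
NULL

# Strict TSV dialect shared by all readers: UTF-8, tab-separated, '#'-prefixed
# comment lines ignored, every row must have the header's width (missing cells
# are errors, never zeros), numeric cells must parse completely.
.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; restore it
  cells <- lapply(seq_along(cells), function(i) {
    v <- cells[[i]]
    n <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE))) + 1L
    c(v, rep("", n - length(v)))
  })
  header <- cells[[1]]
  body <- cells[-1]
  width <- length(header)
  bad <- which(lengths(body) != width)
  if (length(bad))
    stop(sprintf("row %d of %s has %d field(s); expected %d (missing cells are errors)",
                 bad[1] + 1L, basename(path), length(body[[bad[1]]]), width))
  if (any(vapply(body, function(v) any(!nzchar(v)), logical(1))))
    stop("empty cells in ", basename(path), "; missing values are not allowed")
  list(header = header, body = body)
}

.parseNumeric <- function(values, rowLabels, colLabel, path) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !is.na(values))
  if (length(bad))
    stop(sprintf("malformed numeric cell '%s' at row '%s', column '%s' of %s",
                 values[bad[1]], rowLabels[bad[1]], colLabel, basename(path)))
  out
}

#' Read a feature x sample count table
#'
#' Parses a strict TSV (first column feature id, header row of sample ids,
#' \code{#} comment lines ignored) into a validated [CountTable-class].
#' All-zero rows are retained. Feature ids are case-sensitive exact strings;
#' no fuzzy matching is ever attempted.
#'
#' @param path TSV file path.
#' @param layer,featureKind tags for the resulting table (see
#'   [CountTable-class]).
#' @param sampleData optional metadata from [readSampleMeta()].
#' @return a [CountTable-class].
#' @export
readCountTable <- function(path, layer, featureKind, sampleData = NULL) {
  tsv <- .readTsv(path)
  samples <- tsv$header[-1]
  ids <- vapply(tsv$body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicated feature id(s) in ", basename(path), ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    m[, j] <- .parseNumeric(vapply(tsv$body, `[`, character(1), j + 1L),
                            ids, samples[j], path)
  }
  if (any(m < 0))
    stop("negative count(s) in ", basename(path))
  stopifnot(length(tsv$body) == nrow(m)) # parsing never silently drops rows
  CountTable(m, layer = layer, featureKind = featureKind,
             sampleData = sampleData)
}

#' Read sample metadata
#'
#' TSV with columns \code{sample_id}, \code{day}, \code{treatment},
#' \code{tank}, \code{layer}, \code{tech_replicate_group}. Checks that
#' sample ids are unique within a layer, days belong to the configured
#' ordered day list, and every metaproteome run carries a technical-replicate
#' group (runs sharing a group id are repeat injections of one biological
#' sample).
#'
#' @param path TSV file path.
#' @param days ordered vector of allowed experimental days.
#' @return data.frame of validated metadata.
#' @export
readSampleMeta <- function(path, days = c(1, 5, 8, 12)) {
  tsv <- .readTsv(path)
  need <- c("sample_id", "day", "treatment", "tank", "layer",
            "tech_replicate_group")
  if (!setequal(tsv$header, need))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(do.call(rbind, tsv$body), stringsAsFactors = FALSE)
  names(df) <- tsv$header
  df <- df[need]
  df$day <- .parseNumeric(df$day, df$sample_id, "day", path)
  validateSampleMeta(df, days = days)
  df
}

#' Validate a sample-metadata data.frame
#' @param meta data.frame as returned by [readSampleMeta()].
#' @param days ordered vector of allowed experimental days.
#' @return invisibly, the validated metadata.
#' @export
validateSampleMeta <- function(meta, days = sort(unique(meta$day))) {
  for (ly in unique(meta$layer)) {
    ids <- meta$sample_id[meta$layer == ly]
    if (anyDuplicated(ids))
      stop("duplicated sample id(s) within layer ", ly, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(meta$layer %in% .LAYERS))
    stop("layer must be one of: ", paste(.LAYERS, collapse = ", "))
  bad <- setdiff(unique(meta$day), days)
  if (length(bad))
    stop("day(s) outside the configured day list: ",
         paste(bad, collapse = ", "))
  mp <- meta[meta$layer == "metaproteome", , drop = FALSE]
  if (nrow(mp) && any(!nzchar(mp$tech_replicate_group)))
    stop("every metaproteome run needs a tech_replicate_group")
  invisible(meta)
}

#' Read an Abacus-style protein table
#'
#' Strict TSV with columns \code{protein_id}, \code{probability},
#' \code{unique_peptides}, \code{length}, followed by one spectral-count
#' column per mass-spectrometry run. Run ids are taken from the header and,
#' when metadata are supplied, checked against it.
#'
#' @param path TSV file path.
#' @param sampleData optional metadata from [readSampleMeta()]; every run
#'   column must then appear among the metaproteome sample ids.
#' @return a [ProteinSet-class].
#' @export
readProteinTable <- function(path, sampleData = NULL) {
  tsv <- .readTsv(path)
  fixed <- c("protein_id", "probability", "unique_peptides", "length")
  if (!identical(tsv$header[seq_along(fixed)], fixed))
    stop("protein table must start with columns: ",
         paste(fixed, collapse = ", "),
         if (!"length" %in% tsv$header) " (no length column: NSAF impossible)")
  runs <- tsv$header[-seq_along(fixed)]
  if (!length(runs)) stop("protein table has no spectral-count columns")
  if (!is.null(sampleData)) {
    known <- sampleData$sample_id[sampleData$layer == "metaproteome"]
    bad <- setdiff(runs, known)
    if (length(bad))
      stop("run id(s) absent from metadata: ", paste(bad, collapse = ", "))
  }
  ids <- vapply(tsv$body, `[`, character(1), 1L)
  grab <- function(j, lab) .parseNumeric(vapply(tsv$body, `[`, character(1), j),
                                         ids, lab, path)
  info <- data.frame(protein_id = ids,
                     probability = grab(2L, "probability"),
                     unique_peptides = grab(3L, "unique_peptides"),
                     length = grab(4L, "length"),
                     stringsAsFactors = FALSE)
  spectra <- matrix(NA_real_, nrow = length(ids), ncol = length(runs),
                    dimnames = list(ids, runs))
  for (j in seq_along(runs))
    spectra[, j] <- grab(j + 4L, runs[j])
  info <- info[c("protein_id", "length", "probability", "unique_peptides")]
  ProteinSet(info, spectra)
}

#' Read protein annotation maps
#'
#' Merges up to three two-column strict TSVs into an [AnnotationMap-class]:
#' \code{taxonomy} (protein_id, semicolon-delimited lineage), \code{go}
#' (protein_id, GO id; one row per assignment) and optionally \code{length}
#' (protein_id, amino acids). Proteins present in one file but not another
#' are kept and reported by [unannotated()] rather than dropped.
#'
#' @param taxonomy,go,length TSV paths; \code{length} may be NULL.
#' @return an [AnnotationMap-class].
#' @export
readAnnotationMap <- function(taxonomy, go, length = NULL) {
  two <- function(path) {
    tsv <- .readTsv(path)
    if (length(tsv$header) != 2L)
      stop("expected a two-column TSV: ", basename(path))
    data.frame(protein_id = vapply(tsv$body, `[`, character(1), 1L),
               value = vapply(tsv$body, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  }
  tx <- two(taxonomy)
  if (anyDuplicated(tx$protein_id))
    stop("duplicated taxonomy rows for protein(s): ",
         paste(unique(tx$protein_id[duplicated(tx$protein_id)]), collapse = ", "))
  lineages <- stats::setNames(tx$value, tx$protein_id)
  gf <- two(go)
  goTerms <- lapply(split(gf$value, gf$protein_id), unique)
  lens <- numeric()
  if (!is.null(length)) {
    lf <- two(length)
    val <- .parseNumeric(lf$value, lf$protein_id, "length", length)
    agg <- split(val, lf$protein_id)
    conflict <- names(agg)[vapply(agg, function(v) length(unique(v)) > 1L,
                                  logical(1))]
    if (base::length(conflict))
      stop("conflicting lengths for protein(s): ",
           paste(conflict, collapse = ", "))
    lens <- vapply(agg, `[`, numeric(1), 1L)
  }
  AnnotationMap(lineages = lineages, goTerms = goTerms, lengths = lens)
}

#' Write a tabular result as strict TSV
#'
#' Deterministic column order (as given), UTF-8, floats rendered with six
#' significant digits so repeated runs produce byte-identical files.
#'
#' @param x data.frame (an empty one yields a header-only file).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTable <- function(x, path) {
  x <- as.data.frame(x)
  fmt <- function(col) {
    if (is.double(col)) {
      out <- formatC(col, digits = 6, format = "g")
      # whole-valued counts render exactly, however large
      whole <- is.finite(col) & col == floor(col) & abs(col) < 2^53
      out[whole] <- formatC(col[whole], format = "f", digits = 0)
      out
    } else as.character(col)
  }
  lines <- paste(names(x), collapse = "\t")
  if (nrow(x)) {
    cols <- lapply(x, fmt)
    lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a CountTable as strict TSV
#'
#' First column \code{feature_id}, then one column per sample; integral
#' counts render as integers, averaged (real) counts with six significant
#' digits. \code{readCountTable(writeCountTable(x))} reproduces labels and
#' counts exactly for integer tables and to rendering precision otherwise.
#'
#' @param x a [CountTable-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeCountTable <- function(x, path) {
  m <- counts(x)
  df <- data.frame(feature_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTable(df, path)
}

#' Write a ProteinSet in the schema readProteinTable() expects
#' @param x a [ProteinSet-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeProteinTable <- function(x, path) {
  info <- proteinInfo(x)
  df <- data.frame(protein_id = info$protein_id,
                   probability = info$probability,
                   unique_peptides = info$unique_peptides,
                   length = info$length,
                   as.data.frame(spectralCounts(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTable(df, path)
}
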