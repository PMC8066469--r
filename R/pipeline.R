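#' @include io.R quant.R concordance.R diversity.R anosim.R nmds.R godiff.R simulate.R
NULL

#' Run the full coupled-omics pipeline on a simulated dataset
#'
#' Generates a coupled dataset from \code{config}, writes the input tables
#' in the package's strict TSV schemas, reads them back through the
#' validated readers, and runs every analysis stage: protein-evidence
#' filtering, technical-replicate averaging, NSAF, taxon/GO aggregation,
#' per-library diversity, Bray-Curtis + NMDS + ANOSIM on the NSAF table,
#' per-condition read-versus-PSM concordance, first-zeroed temporal deltas,
#' per-taxon activity bias, cross-layer presence/absence, and pairwise
#' differential GO tests with per-taxon contributions for significant terms.
#' All randomness derives from \code{config@seed}, so two runs with the same
#' config produce byte-identical output TSVs.
#'
#' @param outDir output directory (created if absent).
#' @param config a [SimulationConfig-class].
#' @param minUnique,minProbability protein-evidence thresholds
#'   (see [filterProteins()]).
#' @param alpha,pseudo GO differential test parameters
#'   (see [pairwiseGoTests()]).
#' @param nPerm ANOSIM permutations.
#' @param rank taxonomic reporting rank.
#' @return invisibly, a list of the in-memory results (count tables,
#'   data.frames, [AnosimResult-class]s, [NmdsResult-class] and the
#'   [recoveryReport()]).
#' @export
runPipeline <- function(outDir, config = simulationConfig(),
                        minUnique = 2, minProbability = 0.93,
                        alpha = 0.05, pseudo = 1, nPerm = 999,
                        rank = "Class") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outDir, f)
  sim <- simulateCoupledOmics(config)

  # ---- write inputs in the exchange schemas, then re-read them ----
  writeCountTable(sim$metagenomeTaxa, path("input_metagenome_taxa.tsv"))
  writeCountTable(sim$metagenomeGo, path("input_metagenome_go.tsv"))
  writeProteinTable(sim$proteins, path("input_proteins.tsv"))
  writeTable(sim$sampleMeta, path("input_sample_meta.tsv"))
  pr <- config@proteins
  writeTable(data.frame(protein_id = pr$protein_id,
                        lineage = config@taxa$lineage[
                          match(pr$taxon, config@taxa$taxon)]),
             path("input_annotations_taxonomy.tsv"))
  goDf <- data.frame(
    protein_id = rep(names(config@goAssign), lengths(config@goAssign)),
    go_term = unlist(config@goAssign, use.names = FALSE))
  writeTable(goDf, path("input_annotations_go.tsv"))

  meta <- readSampleMeta(path("input_sample_meta.tsv"), days = config@days)
  mgTaxa <- readCountTable(path("input_metagenome_taxa.tsv"),
                           layer = "metagenome", featureKind = "taxon",
                           sampleData = meta)
  mgGo <- readCountTable(path("input_metagenome_go.tsv"),
                         layer = "metagenome", featureKind = "go_term",
                         sampleData = meta)
  proteins <- readProteinTable(path("input_proteins.tsv"), sampleData = meta)
  ann <- readAnnotationMap(path("input_annotations_taxonomy.tsv"),
                           path("input_annotations_go.tsv"))

  # ---- metaproteome quantification ----
  kept <- filterProteins(proteins, minUnique = minUnique,
                         minProbability = minProbability)
  protRuns <- proteinCountTable(kept, sampleData = meta)
  protAvg <- averageTechnicalReplicates(protRuns, meta)
  lengths <- stats::setNames(proteinInfo(kept)$length,
                             proteinInfo(kept)$protein_id)
  nsaf <- computeNSAF(protAvg, lengths)
  mpTaxa <- aggregatePSMs(protAvg, ann, level = "taxon", rank = rank)
  mpGo <- aggregatePSMs(protAvg, ann, level = "go_term")
  writeCountTable(nsaf, path("protein_nsaf.tsv"))
  writeCountTable(mpTaxa, path("metaproteome_taxa.tsv"))
  writeCountTable(mpGo, path("metaproteome_go.tsv"))

  # ---- diversity and community structure ----
  diversity <- diversityTable(mgTaxa)
  writeTable(diversity, path("diversity.tsv"))
  bc <- brayCurtis(nsaf)
  writeTable(data.frame(sample_id = rownames(bc), as.data.frame(bc),
                        check.names = FALSE), path("bray_curtis.tsv"))
  nsafMeta <- sampleMeta(nsaf)
  ord <- nmds(bc, k = 2, seed = config@seed + 3L)
  writeTable(data.frame(sample_id = rownames(nmdsPoints(ord)),
                        as.data.frame(nmdsPoints(ord)),
                        stress = nmdsStress(ord)),
             path("nmds_coordinates.tsv"))
  anosimDay <- anosim(bc, nsafMeta$day, nPerm = nPerm,
                      seed = config@seed + 4L)
  anosimTrt <- anosim(bc, nsafMeta$treatment, nPerm = nPerm,
                      seed = config@seed + 5L)
  writeTable(data.frame(
    grouping = c("day", "treatment"),
    r_statistic = c(anosimR(anosimDay), anosimR(anosimTrt)),
    p_value = c(anosimP(anosimDay), anosimP(anosimTrt)),
    n_permutations = nPerm), path("anosim.tsv"))

  # ---- read-versus-PSM concordance ----
  concTaxa <- concordanceByCondition(mgTaxa, mpTaxa, dayOrder = config@days)
  concGo <- concordanceByCondition(mgGo, mpGo, dayOrder = config@days)
  writeTable(concTaxa, path("concordance_taxa.tsv"))
  writeTable(concGo, path("concordance_go.tsv"))
  deltasTaxa <- temporalDeltas(conditionRatios(mgTaxa),
                               dayOrder = config@days)
  deltasGo <- temporalDeltas(conditionRatios(mpGo), dayOrder = config@days)
  writeTable(deltasTaxa, path("deltas_metagenome_taxa.tsv"))
  writeTable(deltasGo, path("deltas_metaproteome_go.tsv"))
  bias <- activityBiasTable(mgTaxa, mpTaxa)
  writeTable(bias, path("activity_bias.tsv"))
  presence <- crossLayerPresence(mgTaxa, mpTaxa)
  writeTable(presence, path("presence.tsv"))

  # ---- differential GO analysis (prokaryote-annotated proteins only) ----
  prok <- intersect(rownames(protAvg), prokaryoteIds(ann))
  goPsm <- aggregatePSMs(protAvg[prok, ], ann, level = "go_term")
  goDiff <- pairwiseGoTests(goPsm, alpha = alpha, pseudo = pseudo,
                            dayOrder = config@days)
  writeTable(goDiff, path("go_differential.tsv"))
  sig <- goDiff[goDiff$significant & goDiff$go_term != "unassigned", ]
  contrib <- list()
  for (i in seq_len(nrow(sig))) {
    for (cond in c(sig$condition_a[i], sig$condition_b[i])) {
      d <- as.numeric(sub("^d([0-9.]+)_.*$", "\\1", cond))
      trt <- sub("^d[0-9.]+_", "", cond)
      res <- tryCatch(
        taxonContributions(protAvg[prok, ], ann, sig$go_term[i], d, trt,
                           rank = rank),
        error = function(e) NULL)
      if (!is.null(res)) contrib[[paste(sig$go_term[i], cond)]] <- res
    }
  }
  contrib <- if (length(contrib)) unique(do.call(rbind, contrib)) else
    data.frame(go_term = character(), day = numeric(),
               treatment = character(), taxon = character(),
               psm = numeric(), fraction = numeric())
  writeTable(contrib, path("taxon_contributions.tsv"))

  recovery <- recoveryReport(sim$truth, bias, concordance = concTaxa,
                             presence = presence)
  writeTable(recovery$bias, path("recovery_bias.tsv"))

  invisible(list(
    sim = sim, meta = meta, proteins = proteins, kept = kept,
    nsaf = nsaf, metagenomeTaxa = mgTaxa, metagenomeGo = mgGo,
    metaproteomeTaxa = mpTaxa, metaproteomeGo = mpGo,
    diversity = diversity, brayCurtis = bc, nmds = ord,
    anosimDay = anosimDay, anosimTreatment = anosimTrt,
    concordanceTaxa = concTaxa, concordanceGo = concGo,
    deltasTaxa = deltasTaxa, deltasGo = deltasGo,
    activityBias = bias, presence = presence,
    goDifferential = goDiff, taxonContributions = contrib,
    recovery = recovery))
}
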