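#' @include quant.R concordance.R
NULL

# 25 mixed Kingdom-through-Class taxonomic groups typical of MEGAN-style
# class-level exports from coastal hatchery water: lineages may stop at the
# kingdom or phylum when reads cannot be placed deeper.
.DEFAULT_TAXA <- data.frame(
  taxon = c("Alphaproteobacteria", "Betaproteobacteria",
            "Gammaproteobacteria", "Deltaproteobacteria",
            "Epsilonproteobacteria", "Flavobacteriia", "Cytophagia",
            "Sphingobacteriia", "Bacteroidia", "Cyanobacteria",
            "Gloeobacteria", "Actinobacteria", "Bacilli", "Clostridia",
            "Planctomycetia", "Verrucomicrobiae", "Verrucomicrobia",
            "Bacteroidetes", "Proteobacteria", "Bacteria", "Chloroflexia",
            "Nitrospira", "Acidimicrobiia", "Archaea", "Thermoplasmata"),
  lineage = c(
    "Bacteria;Proteobacteria;Alphaproteobacteria",
    "Bacteria;Proteobacteria;Betaproteobacteria",
    "Bacteria;Proteobacteria;Gammaproteobacteria",
    "Bacteria;Proteobacteria;Deltaproteobacteria",
    "Bacteria;Proteobacteria;Epsilonproteobacteria",
    "Bacteria;Bacteroidetes;Flavobacteriia",
    "Bacteria;Bacteroidetes;Cytophagia",
    "Bacteria;Bacteroidetes;Sphingobacteriia",
    "Bacteria;Bacteroidetes;Bacteroidia",
    "Bacteria;Cyanobacteria",
    "Bacteria;Cyanobacteria;Gloeobacteria",
    "Bacteria;Actinobacteria",
    "Bacteria;Firmicutes;Bacilli",
    "Bacteria;Firmicutes;Clostridia",
    "Bacteria;Planctomycetes;Planctomycetia",
    "Bacteria;Verrucomicrobia;Verrucomicrobiae",
    "Bacteria;Verrucomicrobia",
    "Bacteria;Bacteroidetes",
    "Bacteria;Proteobacteria",
    "Bacteria",
    "Bacteria;Chloroflexi;Chloroflexia",
    "Bacteria;Nitrospirae;Nitrospira",
    "Bacteria;Actinobacteria;Acidimicrobiia",
    "Archaea",
    "Archaea;Euryarchaeota;Thermoplasmata"),
  stringsAsFactors = FALSE)

# baseline community profile: Alpha-/Gammaproteobacteria and Flavobacteriia
# dominant, a long tail of rarer groups
.DEFAULT_BASE_P <- c(
  Alphaproteobacteria = 0.21, Betaproteobacteria = 0.05,
  Gammaproteobacteria = 0.17, Deltaproteobacteria = 0.03,
  Epsilonproteobacteria = 0.012, Flavobacteriia = 0.11, Cytophagia = 0.05,
  Sphingobacteriia = 0.02, Bacteroidia = 0.015, Cyanobacteria = 0.04,
  Gloeobacteria = 0.01, Actinobacteria = 0.035, Bacilli = 0.012,
  Clostridia = 0.01, Planctomycetia = 0.015, Verrucomicrobiae = 0.012,
  Verrucomicrobia = 0.02, Bacteroidetes = 0.05, Proteobacteria = 0.045,
  Bacteria = 0.06, Chloroflexia = 0.008, Nitrospira = 0.006,
  Acidimicrobiia = 0.01, Archaea = 0.012, Thermoplasmata = 0.008)

# default activity distortion: sulfate reducers and Alphaproteobacteria more
# active than their read share predicts; Beta-, Gammaproteobacteria,
# Cytophagia and Flavobacteriia less
.DEFAULT_MULTIPLIERS <- c(
  Deltaproteobacteria = 4, Alphaproteobacteria = 2, Actinobacteria = 2,
  Cyanobacteria = 2, Betaproteobacteria = 0.4, Cytophagia = 0.35,
  Gammaproteobacteria = 0.6, Flavobacteriia = 0.6)

.DEFAULT_GO <- c(
  "GO:0006810" = "transport",
  "GO:0003824" = "catalytic activity",
  "GO:0000166" = "nucleotide binding",
  "GO:0043168" = "anion binding",
  "GO:0022900" = "electron transport chain",
  "GO:0044424" = "intracellular part",
  "GO:0018298" = "protein-chromophore linkage",
  "GO:0055114" = "oxidation-reduction process",
  "GO:0006412" = "translation",
  "GO:0016020" = "membrane",
  "GO:0005524" = "ATP binding",
  "GO:0008152" = "metabolic process",
  "GO:0009055" = "electron transfer activity",
  "GO:0016491" = "oxidoreductase activity",
  "GO:0006096" = "glycolytic process",
  "GO:0015979" = "photosynthesis",
  "GO:0005975" = "carbohydrate metabolic process",
  "GO:0006520" = "amino acid metabolic process",
  "GO:0046872" = "metal ion binding",
  "GO:0016787" = "hydrolase activity",
  "GO:0003735" = "structural constituent of ribosome",
  "GO:0051536" = "iron-sulfur cluster binding",
  "GO:0009399" = "nitrogen fixation",
  "GO:0019825" = "oxygen binding",
  "GO:0006950" = "response to stress",
  "GO:0042026" = "protein refolding",
  "GO:0006508" = "proteolysis",
  "GO:0016301" = "kinase activity",
  "GO:0005215" = "transporter activity",
  "GO:0030246" = "carbohydrate binding")

#' Build a coupled-omics simulation design
#'
#' Draws, under one seed, the full design of a synthetic hatchery-water
#' experiment: 25 mixed Kingdom-through-Class taxa, per-taxon proportion
#' trajectories over days x treatments (piecewise-constant with seeded
#' bloom-like jumps), per-taxon activity multipliers distorting the PSM
#' layer, taxon dropout per layer, and each taxon's protein complement
#' (lengths, within-taxon expression shares, GO assignments, and simulated
#' evidence scores). Most proteins carry high posterior probabilities and
#' >= 2 pooled unique peptides; each taxon additionally carries a couple of
#' low-evidence proteins holding a small fixed slice of its expression,
#' mirroring the empirical pattern that identifications failing evidence
#' filters are low-abundance, so the filter stays approximately
#' expression-neutral.
#'
#' @param seed integer seed for every random element of the design.
#' @param days ordered experimental days.
#' @param treatments treatment labels.
#' @param tanksPerTreatment biological replicates (tanks) per treatment in
#'   the metaproteome layer.
#' @param techReps technical (repeat-injection) runs per proteomics sample.
#' @param nReads reads per metagenome library.
#' @param nPsm PSMs per proteomics biological sample (split across its
#'   technical runs).
#' @param proteinsPerTaxon well-supported proteins per taxon.
#' @param lowEvidencePerTaxon additional low-evidence proteins per taxon.
#' @param lowEvidenceShare fraction of a taxon's expression carried by its
#'   low-evidence proteins.
#' @param multipliers named positive numeric of activity multipliers
#'   (unnamed taxa get 1).
#' @param dropoutProteome,dropoutGenome taxa structurally absent from a
#'   layer.
#' @param jumpProb,jumpSd probability and log-scale size of per-day
#'   trajectory jumps (shared across treatments, so community change is
#'   dominated by time).
#' @param treatmentSd log-scale size of the treatment-specific perturbation
#'   of each condition's proportions (small relative to \code{jumpSd}).
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L,
                             days = c(1, 5, 8, 12),
                             treatments = c("pH7.1", "pH8.2"),
                             tanksPerTreatment = 2L,
                             techReps = 3L,
                             nReads = 1e6,
                             nPsm = 2e4,
                             proteinsPerTaxon = 8L,
                             lowEvidencePerTaxon = 2L,
                             lowEvidenceShare = 0.02,
                             multipliers = .DEFAULT_MULTIPLIERS,
                             dropoutProteome = c("Thermoplasmata",
                                                 "Nitrospira",
                                                 "Chloroflexia"),
                             dropoutGenome = character(),
                             jumpProb = 0.3, jumpSd = 0.5,
                             treatmentSd = 0.08) {
  taxa <- .DEFAULT_TAXA
  nt <- nrow(taxa)
  mult <- stats::setNames(rep(1, nt), taxa$taxon)
  mult[names(multipliers)] <- multipliers
  base <- .DEFAULT_BASE_P[taxa$taxon]
  base <- base / sum(base)
  withr::with_seed(as.integer(seed), {
    conds <- expand.grid(day = days, treatment = treatments,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    p <- matrix(0, nt, nrow(conds),
                dimnames = list(taxa$taxon,
                                .conditionKey(conds$day, conds$treatment)))
    # day-to-day jumps are shared across treatments (community change is
    # dominated by time); each treatment adds only a small perturbation
    cur <- base * exp(stats::rnorm(nt, 0, 0.15))
    for (d in days) {
      if (d != days[1]) {
        jump <- stats::rbinom(nt, 1, jumpProb) * stats::rnorm(nt, 0, jumpSd)
        cur <- cur * exp(jump)
      }
      for (trt in treatments) {
        v <- cur * exp(stats::rnorm(nt, 0, treatmentSd))
        v[taxa$taxon %in% dropoutGenome] <- 0
        p[, .conditionKey(d, trt)] <- v / sum(v)
      }
    }
    protRows <- lapply(seq_len(nt), function(i) {
      nReal <- proteinsPerTaxon
      nLow <- lowEvidencePerTaxon
      ids <- sprintf("%s_p%02d", gsub("[^A-Za-z]", "", taxa$taxon[i]),
                     seq_len(nReal + nLow))
      len <- round(stats::runif(nReal + nLow, 100, 900))
      sReal <- stats::rgamma(nReal, shape = 1.2)
      sReal <- sReal / sum(sReal) * (1 - lowEvidenceShare)
      sLow <- stats::rgamma(nLow, shape = 1.2)
      sLow <- sLow / sum(sLow) * lowEvidenceShare
      data.frame(
        protein_id = ids, taxon = taxa$taxon[i], length = len,
        share = c(sReal, sLow),
        probability = c(0.93 + 0.07 * stats::rbeta(nReal, 2, 2),
                        stats::runif(nLow, 0.2, 0.99)),
        unique_peptides = c(2 + stats::rpois(nReal, 4),
                            sample(1:2, nLow, replace = TRUE)),
        stringsAsFactors = FALSE)
    })
    proteins <- do.call(rbind, protRows)
    goAssign <- lapply(seq_len(nrow(proteins)), function(i)
      sort(sample(names(.DEFAULT_GO), sample(1:3, 1))))
    names(goAssign) <- proteins$protein_id
  })
  new("SimulationConfig", taxa = taxa, p = p, multipliers = mult,
      dropoutProteome = dropoutProteome, dropoutGenome = dropoutGenome,
      days = as.numeric(days), treatments = treatments,
      tanksPerTreatment = as.integer(tanksPerTreatment),
      techReps = as.integer(techReps),
      nReads = nReads, nPsm = nPsm, proteins = proteins,
      goAssign = goAssign, seed = as.integer(seed))
}

#' @rdname simulationTruth
#' @export
setMethod("simulationTruth", "SimulationConfig", function(x) {
  q <- x@p * x@multipliers[rownames(x@p)]
  q[rownames(q) %in% x@dropoutProteome, ] <- 0
  q <- sweep(q, 2, colSums(q), "/")
  new("SimulationTruth", p = x@p, q = q, multipliers = x@multipliers,
      dropoutProteome = x@dropoutProteome, dropoutGenome = x@dropoutGenome)
})

#' @rdname simulationTruth
#' @export
truthP <- function(x) x@p

#' @rdname simulationTruth
#' @export
truthQ <- function(x) x@q

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d taxa, %d days x %d treatments; %d proteins; seed %d\n",
              nrow(object@taxa), length(object@days),
              length(object@treatments), nrow(object@proteins), object@seed))
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf("SimulationTruth: %d taxa x %d conditions; %d multiplier(s) != 1; %d proteome-dropout taxa\n",
              nrow(object@p), ncol(object@p),
              sum(object@multipliers != 1), length(object@dropoutProteome)))
})

# split a count vector across k bins, each count multinomially with equal
# probabilities (used for technical-replicate splitting)
.splitCounts <- function(counts, k) {
  out <- matrix(0, length(counts), k)
  nz <- which(counts > 0)
  for (i in nz)
    out[i, ] <- stats::rmultinom(1, counts[i], rep(1 / k, k))
  out
}

#' Simulate a coupled metagenome/metaproteome dataset
#'
#' Reads for each metagenome library are drawn multinomially from the
#' condition's taxon proportions p (at protein-gene resolution, weighted by
#' within-taxon shares, so taxon margins are exactly multinomial at p and a
#' GO-level read table follows from the same draw). PSMs for each proteomics
#' biological sample are drawn multinomially from the activity-distorted
#' proportions q = p * a / sum(p * a), apportioned to the taxon's proteins
#' proportional to length x share, and split multinomially across technical
#' runs. Dropout taxa get structural zeros in their layer. Fully reproducible
#' given the config's seed.
#'
#' @param config a [SimulationConfig-class].
#' @return list with components \code{metagenomeTaxa}, \code{metagenomeGo}
#'   (read-layer [CountTable-class]s), \code{proteins} (a
#'   [ProteinSet-class] of per-run spectral counts), \code{annotations}
#'   (an [AnnotationMap-class]), \code{sampleMeta} (both layers) and
#'   \code{truth} (a [SimulationTruth-class]).
#' @export
simulateCoupledOmics <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  truth <- simulationTruth(config)
  pr <- config@proteins
  nt <- nrow(config@taxa)
  taxIdx <- match(pr$taxon, config@taxa$taxon)
  # read-layer protein weights: within-taxon expression share
  wRead <- pr$share
  # PSM-layer protein weights: length x share, renormalized within taxon
  wPsm <- pr$length * pr$share
  wPsm <- wPsm / stats::ave(wPsm, pr$taxon, FUN = sum)
  wRead <- wRead / stats::ave(wRead, pr$taxon, FUN = sum)

  conds <- colnames(config@p)
  condDay <- as.numeric(sub("^d([0-9.]+)_.*$", "\\1", conds))
  condTrt <- sub("^d[0-9.]+_", "", conds)

  mgIds <- sprintf("MG_%s", conds)
  mgMeta <- data.frame(sample_id = mgIds, day = condDay,
                       treatment = condTrt, tank = "T1",
                       layer = "metagenome", tech_replicate_group = mgIds,
                       stringsAsFactors = FALSE)
  bio <- expand.grid(cond = conds, tank = seq_len(config@tanksPerTreatment),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  bioIds <- sprintf("MP_%s_T%d", bio$cond, bio$tank)
  runIds <- as.vector(t(outer(bioIds, seq_len(config@techReps),
                              function(b, r) sprintf("%s_r%d", b, r))))
  mpMeta <- data.frame(
    sample_id = runIds,
    day = rep(condDay[match(bio$cond, conds)], each = config@techReps),
    treatment = rep(condTrt[match(bio$cond, conds)], each = config@techReps),
    tank = rep(sprintf("T%d", bio$tank), each = config@techReps),
    layer = "metaproteome",
    tech_replicate_group = rep(bioIds, each = config@techReps),
    stringsAsFactors = FALSE)
  meta <- rbind(mgMeta, mpMeta)

  withr::with_seed(config@seed + 1000L, {
    readsProt <- vapply(seq_along(conds), function(ci) {
      prob <- truth@p[taxIdx, ci] * wRead
      as.numeric(stats::rmultinom(1, config@nReads, prob))
    }, numeric(nrow(pr)))
    dimnames(readsProt) <- list(pr$protein_id, mgIds)
    spectra <- matrix(0, nrow(pr), length(runIds),
                      dimnames = list(pr$protein_id, runIds))
    for (b in seq_along(bioIds)) {
      ci <- match(bio$cond[b], conds)
      prob <- truth@q[taxIdx, ci] * wPsm
      psm <- as.numeric(stats::rmultinom(1, config@nPsm, prob))
      runs <- .splitCounts(psm, config@techReps)
      spectra[, (b - 1L) * config@techReps + seq_len(config@techReps)] <- runs
    }
  })

  ann <- AnnotationMap(
    lineages = stats::setNames(config@taxa$lineage[taxIdx], pr$protein_id),
    goTerms = config@goAssign,
    lengths = stats::setNames(as.numeric(pr$length), pr$protein_id))

  readsTable <- CountTable(readsProt, layer = "metagenome",
                           featureKind = "protein", sampleData = mgMeta)
  metagenomeTaxa <- aggregatePSMs(readsTable, ann, level = "taxon",
                                  rank = "Class")
  metagenomeGo <- aggregatePSMs(readsTable, ann, level = "go_term")

  proteins <- ProteinSet(
    pr[c("protein_id", "length", "probability", "unique_peptides")],
    spectra)

  list(metagenomeTaxa = metagenomeTaxa, metagenomeGo = metagenomeGo,
       proteins = proteins, annotations = ann, sampleMeta = meta,
       truth = truth)
}

#' Recovery of simulation ground truth by the pipeline
#'
#' Compares per-taxon activity-bias estimates against the generating truth
#' log2(q/p), summarizes concordance R-squared, and cross-tabulates the
#' presence/absence classification against the structural dropout set.
#'
#' @param truth a [SimulationTruth-class].
#' @param bias data.frame from [activityBiasTable()].
#' @param concordance optional data.frame from [concordanceByCondition()].
#' @param presence optional data.frame from [crossLayerPresence()].
#' @return list with \code{bias} (per-taxon true vs estimated mean log2
#'   bias and absolute error, over taxa present in both layers),
#'   \code{maeLog2Bias}, \code{meanRSquared} (NA when no concordance table),
#'   and \code{presenceConfusion} (counts of presence calls split by dropout
#'   membership; NULL when no presence table).
#' @export
recoveryReport <- function(truth, bias, concordance = NULL, presence = NULL) {
  stopifnot(is(truth, "SimulationTruth"))
  taxa <- rownames(truth@p)
  bad <- setdiff(unique(bias$feature_id), taxa)
  if (length(bad))
    stop("estimates for taxa not in the truth: ", paste(bad, collapse = ", "))
  keep <- taxa[rowSums(truth@p == 0) == 0 & rowSums(truth@q == 0) == 0]
  trueBias <- rowMeans(log2(truth@q[keep, , drop = FALSE] /
                              truth@p[keep, , drop = FALSE]))
  est <- vapply(keep, function(t)
    mean(bias$log2_bias[bias$feature_id == t]), numeric(1))
  df <- data.frame(taxon = keep, true_log2_bias = unname(trueBias),
                   est_log2_bias = unname(est),
                   abs_error = abs(unname(est - trueBias)),
                   stringsAsFactors = FALSE, row.names = NULL)
  confusion <- NULL
  if (!is.null(presence)) {
    dropped <- presence$feature_id %in% truth@dropoutProteome
    confusion <- table(dropout = ifelse(dropped, "proteome_dropout", "kept"),
                       status = presence$status)
  }
  list(bias = df,
       maeLog2Bias = mean(df$abs_error),
       meanRSquared = if (is.null(concordance)) NA_real_
                      else mean(concordance$r_squared),
       presenceConfusion = confusion)
}
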