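# Shared in-code fixtures: everything is built programmatically so tests run
# from a clean tree.

toyMatrix <- function(nf = 5, ns = 4, lambda = 20, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nf * ns, lambda), nf, ns,
                dimnames = list(paste0("f", seq_len(nf)),
                                paste0("s", seq_len(ns))))
  })
  m
}

toyCountTable <- function(nf = 5, ns = 4, lambda = 20, seed = 1,
                          layer = "metagenome", featureKind = "taxon") {
  CountTable(toyMatrix(nf, ns, lambda, seed), layer = layer,
             featureKind = featureKind)
}

# the 4-protein worked example: unique peptides (1,2,3,2),
# probabilities (0.95, 0.99, 0.90, 0.95)
toyProteins <- function(runs = paste0("r", 1:2)) {
  info <- data.frame(
    protein_id = paste0("P", 1:4),
    length = c(100, 200, 150, 300),
    probability = c(0.95, 0.99, 0.90, 0.95),
    unique_peptides = c(1, 2, 3, 2))
  spectra <- matrix(seq_len(4 * length(runs)), nrow = 4,
                    dimnames = list(info$protein_id, runs))
  ProteinSet(info, spectra)
}

toyAnnotation <- function() {
  AnnotationMap(
    lineages = c(P1 = "Bacteria;Proteobacteria;Alphaproteobacteria",
                 P2 = "Bacteria;Proteobacteria;Alphaproteobacteria",
                 P3 = "Bacteria;Bacteroidetes",
                 P4 = ""),
    goTerms = list(P1 = c("GO:A", "GO:B"), P2 = "GO:A", P3 = "GO:C"),
    lengths = c(P1 = 100, P2 = 200, P3 = 150, P4 = 300))
}

toyRunMeta <- function(runs = paste0("r", 1:6), groups = rep(c("g1", "g2"), each = 3),
                       day = 1, treatment = "pH7.1") {
  data.frame(sample_id = runs, day = day, treatment = treatment,
             tank = "T1", layer = "metaproteome",
             tech_replicate_group = groups, stringsAsFactors = FALSE)
}

# a condition-design metadata table: one sample per (day, treatment)
conditionMeta <- function(days = c(1, 5, 8, 12),
                          treatments = c("pH7.1", "pH8.2"),
                          layer = "metagenome", prefix = "S") {
  g <- expand.grid(day = days, treatment = treatments,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ids <- sprintf("%s_d%g_%s", prefix, g$day, g$treatment)
  data.frame(sample_id = ids, day = g$day, treatment = g$treatment,
             tank = "T1", layer = layer, tech_replicate_group = ids,
             stringsAsFactors = FALSE)
}

# small simulation config for fast tests
smallConfig <- function(seed = 1, ...) {
  simulationConfig(seed = seed, nReads = 5e4, nPsm = 5e3, ...)
}
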