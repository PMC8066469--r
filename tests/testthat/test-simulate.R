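test_that("the generator is deterministic given its seed", {
  a <- simulateCoupledOmics(smallConfig(seed = 3))
  b <- simulateCoupledOmics(smallConfig(seed = 3))
  expect_identical(counts(a$metagenomeTaxa), counts(b$metagenomeTaxa))
  expect_identical(spectralCounts(a$proteins), spectralCounts(b$proteins))
  c <- simulateCoupledOmics(smallConfig(seed = 4))
  expect_false(identical(counts(a$metagenomeTaxa),
                         counts(c$metagenomeTaxa)))
})

test_that("library totals are conserved exactly (multinomial draws)", {
  cfg <- smallConfig(seed = 5)
  sim <- simulateCoupledOmics(cfg)
  expect_true(all(colSums(counts(sim$metagenomeTaxa)) == cfg@nReads))
  spc <- spectralCounts(sim$proteins)
  grp <- sim$sampleMeta$tech_replicate_group[
    match(colnames(spc), sim$sampleMeta$sample_id)]
  perSample <- tapply(colSums(spc), grp, sum)
  expect_true(all(perSample == cfg@nPsm))
})

test_that("the design shape matches the emulated experiment", {
  cfg <- smallConfig(seed = 1)
  sim <- simulateCoupledOmics(cfg)
  expect_equal(nrow(cfg@taxa), 25L)
  expect_equal(sort(unique(sim$sampleMeta$day)), c(1, 5, 8, 12))
  expect_setequal(unique(sim$sampleMeta$treatment), c("pH7.1", "pH8.2"))
  mp <- sim$sampleMeta[sim$sampleMeta$layer == "metaproteome", ]
  expect_equal(length(unique(mp$tech_replicate_group)), 16L) # 2 trt x 4 d x 2 tanks
  expect_true(all(table(mp$tech_replicate_group) == 3L))
  # mixed-rank lineages: some stop at Kingdom or Phylum
  depths <- lengths(strsplit(cfg@taxa$lineage, ";"))
  expect_setequal(unique(depths), 1:3)
})

test_that("truth obeys q = p*a/sum(p*a) and collapses when a = 1", {
  cfg <- smallConfig(seed = 2)
  tr <- simulationTruth(cfg)
  a <- tr@multipliers[rownames(truthP(tr))]
  manual <- truthP(tr) * a
  manual[rownames(manual) %in% cfg@dropoutProteome, ] <- 0
  manual <- sweep(manual, 2, colSums(manual), "/")
  expect_equal(truthQ(tr), manual, tolerance = 1e-12)

  flat <- smallConfig(seed = 2, multipliers = numeric(),
                      dropoutProteome = character())
  trf <- simulationTruth(flat)
  expect_equal(truthQ(trf), truthP(trf), tolerance = 1e-12)
})

test_that("dropout taxa are structural zeros in the proteome layer", {
  cfg <- smallConfig(seed = 6)
  sim <- simulateCoupledOmics(cfg)
  pr <- cfg@proteins
  dropProts <- pr$protein_id[pr$taxon %in% cfg@dropoutProteome]
  expect_true(all(spectralCounts(sim$proteins)[dropProts, ] == 0))
  expect_true(all(counts(sim$metagenomeTaxa)[cfg@dropoutProteome, ] > 0))
})

test_that("an activity multiplier shifts the PSM share in the right direction", {
  hits <- 0L
  for (s in 1:10) {
    cfg <- simulationConfig(seed = 100 + s, nReads = 2e4, nPsm = 2e4,
                            multipliers = c(Deltaproteobacteria = 4),
                            dropoutProteome = character())
    sim <- simulateCoupledOmics(cfg)
    mpTaxa <- aggregatePSMs(
      averageTechnicalReplicates(
        proteinCountTable(sim$proteins, sampleData = sim$sampleMeta),
        sim$sampleMeta),
      sim$annotations, "taxon", rank = "Class")
    bias <- activityBiasTable(sim$metagenomeTaxa, mpTaxa)
    est <- mean(bias$log2_bias[bias$feature_id == "Deltaproteobacteria"])
    if (est > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("recovery report flags taxa mismatches and summarizes error", {
  cfg <- smallConfig(seed = 8)
  sim <- simulateCoupledOmics(cfg)
  mpTaxa <- aggregatePSMs(
    averageTechnicalReplicates(
      proteinCountTable(sim$proteins, sampleData = sim$sampleMeta),
      sim$sampleMeta),
    sim$annotations, "taxon", rank = "Class")
  bias <- activityBiasTable(sim$metagenomeTaxa, mpTaxa)
  rep <- recoveryReport(sim$truth, bias)
  expect_true(all(is.finite(rep$bias$abs_error)))
  expect_lt(rep$maeLog2Bias, 0.5)
  bad <- bias
  bad$feature_id[1] <- "NotATaxon"
  expect_error(recoveryReport(sim$truth, bad), "NotATaxon")
})
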