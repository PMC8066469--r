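test_that("evidence filter applies both thresholds and preserves order", {
  ps <- toyProteins()
  kept <- filterProteins(ps, minUnique = 2, minProbability = 0.93)
  expect_identical(proteinInfo(kept)$protein_id, c("P2", "P4"))
  expect_identical(proteinInfo(filterProteins(ps, 0, 0)), proteinInfo(ps))
  empty <- filterProteins(ps, 10, 1)
  expect_length(empty, 0L)
  expect_error(filterProteins(ps, minUnique = -1), "minUnique")
  # input untouched
  expect_length(ps, 4L)
})

test_that("technical replicates average to one column per group", {
  m <- matrix(c(3, 6, 5, 10, 4, 8, 1, 2, 1, 4, 1, 6), nrow = 2,
              dimnames = list(c("P1", "P2"), paste0("r", 1:6)))
  ct <- CountTable(m, "metaproteome", "protein")
  meta <- toyRunMeta()
  avg <- averageTechnicalReplicates(ct, meta)
  expect_equal(ncol(avg), 2L)
  expect_equal(counts(avg)["P1", "g1"], mean(c(3, 5, 4)))
  expect_equal(counts(avg)["P2", "g2"], mean(c(2, 4, 6)))
  # idempotent on an already-averaged table
  avg2 <- averageTechnicalReplicates(avg, sampleMeta(avg))
  expect_equal(counts(avg2), counts(avg))
  # a single-run group passes through unchanged
  meta1 <- toyRunMeta(runs = "r1", groups = "solo")
  ct1 <- CountTable(m[, 1, drop = FALSE], "metaproteome", "protein")
  expect_equal(unname(counts(averageTechnicalReplicates(ct1, meta1))),
               unname(m[, 1, drop = FALSE]))
})

test_that("NSAF is length-corrected and sums to one per sample", {
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("P1", "P2"), "s1"))
  ct <- CountTable(m, "metaproteome", "protein")
  nsaf <- computeNSAF(ct, c(P1 = 100, P2 = 200))
  expect_equal(unname(counts(nsaf)[, 1]), c(2 / 3, 1 / 3))

  # equal lengths: NSAF proportional to spectral counts
  m2 <- matrix(c(2, 6, 12), ncol = 1, dimnames = list(paste0("P", 1:3), "s1"))
  nsaf2 <- computeNSAF(CountTable(m2, "metaproteome", "protein"),
                       c(P1 = 50, P2 = 50, P3 = 50))
  expect_equal(unname(counts(nsaf2)[, 1]), c(0.1, 0.3, 0.6))

  # a single detected protein carries the whole sample
  m3 <- matrix(c(7, 0), ncol = 1, dimnames = list(c("P1", "P2"), "s1"))
  nsaf3 <- computeNSAF(CountTable(m3, "metaproteome", "protein"),
                       c(P1 = 10, P2 = 10))
  expect_equal(unname(counts(nsaf3)[, 1]), c(1, 0))

  # random fixture: columns sum to 1 within 1e-9
  withr::with_seed(9, {
    m4 <- matrix(rpois(40, 5), 8, 5,
                 dimnames = list(paste0("P", 1:8), paste0("s", 1:5)))
    m4[, 1] <- m4[, 1] + 1
    L <- setNames(sample(100:900, 8), paste0("P", 1:8))
  })
  m4[1, ] <- m4[1, ] + 1 # guard against an all-zero column
  nsaf4 <- computeNSAF(CountTable(m4, "metaproteome", "protein"), L)
  expect_true(all(abs(colSums(counts(nsaf4)) - 1) < 1e-9))

  mz <- matrix(c(1, 0), ncol = 2,
               dimnames = list("P1", c("ok", "empty")))
  expect_error(computeNSAF(CountTable(mz, "metaproteome", "protein"),
                           c(P1 = 10)), "empty")
})

test_that("aggregation is additive, multi-assigns GO terms and conserves mass", {
  ann <- toyAnnotation()
  m <- matrix(c(5, 7, 3, 4), ncol = 1,
              dimnames = list(paste0("P", 1:4), "s1"))
  ct <- CountTable(m, "metaproteome", "protein")

  tax <- aggregatePSMs(ct, ann, level = "taxon", rank = "Class")
  expect_equal(counts(tax)["Alphaproteobacteria", "s1"], 12)
  # truncated lineage counted at its deepest available rank
  expect_equal(counts(tax)["Bacteroidetes", "s1"], 3)
  expect_equal(counts(tax)["unassigned", "s1"], 4)
  # mass conservation, including unassigned
  expect_equal(colSums(counts(tax)), colSums(m))

  go <- aggregatePSMs(ct, ann, level = "go_term")
  # P1 contributes its full count to each of its terms
  expect_equal(counts(go)["GO:A", "s1"], 5 + 7)
  expect_equal(counts(go)["GO:B", "s1"], 5)
  expect_equal(counts(go)["unassigned", "s1"], 4)

  expect_error(aggregatePSMs(ct, ann, level = "taxon", rank = "Genus"),
               "unknown rank")
})

test_that("aggregating a filtered set equals filtering then aggregating", {
  ann <- toyAnnotation()
  ps <- toyProteins()
  kept <- filterProteins(ps)
  a <- aggregatePSMs(proteinCountTable(kept), ann, "taxon", rank = "Class")
  full <- proteinCountTable(ps)
  b <- aggregatePSMs(full[proteinInfo(kept)$protein_id, ], ann, "taxon",
                     rank = "Class")
  expect_equal(counts(a), counts(b))
})
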