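test_that("smoothed ratio test matches hand evaluations and is antisymmetric", {
  # equal proportions, vanishing pseudocount: ratio goes to 0
  r <- goRatioTest(10, 100, 20, 200, pseudo = 1e-9)
  expect_equal(r$log2Ratio, 0, tolerance = 1e-6)

  # both zero counts: log2((1/201) / (1/101)) with Laplace pseudo = 1
  r0 <- goRatioTest(0, 100, 0, 200, pseudo = 1)
  expect_equal(r0$log2Ratio, log2((1 / 201) / (1 / 101)), tolerance = 1e-12)
  expect_equal(r0$log2Ratio, -0.993, tolerance = 1e-3)

  # doubling counts and totals leaves the smoothed proportion almost fixed
  a <- goRatioTest(50, 1000, 80, 1000, pseudo = 1)
  b <- goRatioTest(100, 2000, 80, 1000, pseudo = 1)
  expect_equal(a$log2Ratio, b$log2Ratio, tolerance = 0.02)

  # antisymmetry under condition swap
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rpois(2, 50); n <- x + rpois(2, 500) + 1
      f <- goRatioTest(x[1], n[1], x[2], n[2])
      g <- goRatioTest(x[2], n[2], x[1], n[1])
      expect_equal(f$log2Ratio, -g$log2Ratio, tolerance = 1e-12)
      expect_equal(f$pValue, g$pValue, tolerance = 1e-12)
    }
  })

  expect_error(goRatioTest(1, 0, 1, 10), "positive")
  expect_error(goRatioTest(5, 4, 1, 10), "psm")
  expect_error(goRatioTest(1, 10, 1, 10, pseudo = 0), "pseudo")
})

test_that("q-value correction is BH step-up with order preserved", {
  expect_equal(correctQvalues(0.02), 0.02)
  expect_equal(correctQvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(correctQvalues(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.04, 0.001, 0.7)
  q <- correctQvalues(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p))
  expect_error(correctQvalues(c(0.5, 0)), "p-values")
})

test_that("condition pooling is the arithmetic mean over matching samples", {
  meta <- conditionMeta(days = 1, treatments = "pH7.1")
  meta <- rbind(meta, within(meta, {sample_id <- "S2"; tank <- "T2"}))
  m <- matrix(c(10, 30, 14, 50), nrow = 2,
              dimnames = list(c("g1", "g2"), meta$sample_id))
  ct <- CountTable(m, "metaproteome", "go_term", sampleData = meta)
  pooled <- poolCondition(ct, 1, "pH7.1")
  expect_equal(unname(pooled), c(12, 40))
  # pooled total is the mean of the sample totals
  expect_equal(sum(pooled), mean(colSums(m)))
  expect_error(poolCondition(ct, 5, "pH7.1"), "no samples")
  single <- CountTable(m[, 1, drop = FALSE], "metaproteome", "go_term",
                       sampleData = meta[1, ])
  expect_equal(unname(poolCondition(single, 1, "pH7.1")), unname(m[, 1]))
})

test_that("pairwise comparisons cover consecutive days and treatments", {
  meta <- conditionMeta(layer = "metaproteome", prefix = "MP")
  withr::with_seed(31, {
    m <- matrix(rpois(10 * nrow(meta), 40) + 1, 10,
                dimnames = list(paste0("GO:", 1:10), meta$sample_id))
  })
  ct <- CountTable(m, "metaproteome", "go_term", sampleData = meta)
  res <- pairwiseGoTests(ct)
  # 3 consecutive-day pairs x 2 treatments + 4 between-treatment days
  expect_equal(length(unique(paste(res$condition_a, res$condition_b))), 10L)
  expect_equal(nrow(res), 10L * 10L)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_identical(res$significant, res$q_value <= 0.05)
})

test_that("taxon contributions partition a term's pooled PSMs", {
  ann <- toyAnnotation()
  meta <- conditionMeta(days = 1, treatments = "pH7.1",
                        layer = "metaproteome", prefix = "MP")
  m <- matrix(c(30, 10, 5, 2), ncol = 1,
              dimnames = list(paste0("P", 1:4), meta$sample_id))
  ct <- CountTable(m, "metaproteome", "protein", sampleData = meta)
  # GO:A is carried by P1 (Alphaproteobacteria, 30) and P2 (same class, 10)
  tc <- taxonContributions(ct, ann, "GO:A", 1, "pH7.1")
  expect_equal(sum(tc$fraction), 1)
  expect_equal(tc$fraction[tc$taxon == "Alphaproteobacteria"], 1)
  # GO:C fed by one class only
  tcC <- taxonContributions(ct, ann, "GO:C", 1, "pH7.1")
  expect_equal(tcC$taxon, "Bacteroidetes")
  expect_equal(tcC$fraction, 1)
  expect_error(taxonContributions(ct, ann, "GO:Z", 1, "pH7.1"),
               "no attributed")
})

test_that("two-taxon contributions split 30:10 as 0.75/0.25", {
  ann <- AnnotationMap(
    lineages = c(P1 = "Bacteria;Cyanobacteria", P2 = "Bacteria;Bacteroidetes"),
    goTerms = list(P1 = "GO:X", P2 = "GO:X"))
  meta <- conditionMeta(days = 1, treatments = "pH7.1",
                        layer = "metaproteome", prefix = "MP")
  m <- matrix(c(30, 10), ncol = 1,
              dimnames = list(c("P1", "P2"), meta$sample_id))
  ct <- CountTable(m, "metaproteome", "protein", sampleData = meta)
  tc <- taxonContributions(ct, ann, "GO:X", 1, "pH7.1")
  expect_equal(sort(tc$fraction), c(0.25, 0.75))
})
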