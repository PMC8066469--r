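test_that("library normalization divides by the column total", {
  m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(paste0("f", 1:3), "s1"))
  r <- normalizeLibrary(CountTable(m, "metagenome", "taxon"))
  expect_equal(unname(counts(r)[, 1]), c(0.2, 0.3, 0.5))

  one <- CountTable(matrix(c(4, 9), 1, 2, dimnames = list("f1", c("a", "b"))),
                    "metagenome", "taxon")
  expect_true(all(counts(normalizeLibrary(one)) == 1))

  ct <- toyCountTable()
  expect_equal(unname(colSums(counts(normalizeLibrary(ct)))),
               rep(1, ncol(ct)))

  mz <- matrix(c(1, 0), 1, 2, dimnames = list("f1", c("ok", "dead")))
  expect_error(normalizeLibrary(CountTable(mz, "metagenome", "taxon")),
               "dead")
})

test_that("temporal deltas zero the first day and telescope", {
  s <- data.frame(feature_id = "f1", treatment = "pH7.1",
                  day = c(1, 5, 8), ratio = c(0.1, 0.3, 0.2))
  d <- temporalDeltas(s)
  expect_equal(d$delta, c(0, 0.2, -0.1))

  const <- data.frame(feature_id = "f1", treatment = "pH7.1",
                      day = c(1, 5, 8, 12), ratio = 0.25)
  expect_equal(temporalDeltas(const)$delta, rep(0, 4))

  dup <- data.frame(feature_id = "f1", treatment = "pH7.1",
                    day = c(1, 1), ratio = c(0.1, 0.2))
  expect_error(temporalDeltas(dup), "duplicate day")

  # a feature unobserved at an observed day gets ratio 0
  two <- data.frame(feature_id = c("f1", "f1", "f2"),
                    treatment = "pH7.1", day = c(1, 5, 1),
                    ratio = c(0.4, 0.6, 0.6))
  d2 <- temporalDeltas(two)
  f2 <- d2[d2$feature_id == "f2", ]
  expect_equal(f2$ratio, c(0.6, 0))
  expect_equal(f2$delta, c(0, -0.6))
})

test_that("telescoping identity holds on random series", {
  withr::with_seed(4, {
    for (i in 1:25) {
      nd <- sample(2:4, 1)
      days <- sort(sample(c(1, 5, 8, 12), nd))
      s <- expand.grid(feature_id = paste0("f", 1:6), day = days,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      s$treatment <- "pH8.2"
      s$ratio <- runif(nrow(s))
      d <- temporalDeltas(s)
      for (f in unique(d$feature_id)) {
        ser <- d[d$feature_id == f, ]
        expect_equal(sum(ser$delta), ser$ratio[nrow(ser)] - ser$ratio[1],
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("concordance regression matches closed-form least squares", {
  perfect <- pairedConcordance(1:5, 1:5)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  expect_equal(perfect$rSquared, 1)

  # a flat PSM profile has no variance for reads to explain
  flat <- pairedConcordance(c(0, 1, 2), c(1, 1, 1))
  expect_equal(flat$slope, 0)
  expect_equal(flat$rSquared, 0)

  # hand-computed OLS: slope = Sxy/Sxx = 2.1/2, R^2 = Sxy^2/(Sxx*Syy)
  fit <- pairedConcordance(c(0, 1, 2), c(0, 0.9, 2.1))
  expect_equal(fit$slope, 1.05)
  expect_equal(fit$intercept, -0.05)
  expect_equal(fit$rSquared, 4.41 / 4.44, tolerance = 1e-9)

  expect_error(pairedConcordance(1, 2), "at least 2")
  expect_error(pairedConcordance(c(a = 1, b = 2), c(a = 1, c = 2)),
               "mismatched feature sets")
})

test_that("activity bias has the right sign, zero and smoothing behaviour", {
  expect_identical(activityBias(0.3, 0.3), 0)
  expect_identical(activityBias(0, 0), 0)
  expect_equal(activityBias(0.1, 0.2), 1, tolerance = 1e-4)
  expect_lt(activityBias(0.2, 0.1), 0)
  expect_error(activityBias(0.1, 0.2, pseudo = 0), "pseudo")
  expect_error(activityBias(1.5, 0.2), "ratios")
})

test_that("cross-layer presence classifies all four states and partitions", {
  meta <- conditionMeta(days = c(1, 5), treatments = "pH7.1")
  mg <- CountTable(matrix(c(100, 0, 50, 0, 80, 0, 60, 0), nrow = 4,
                          dimnames = list(paste0("t", 1:4), meta$sample_id)),
                   "metagenome", "taxon", sampleData = meta)
  metaP <- conditionMeta(days = c(1, 5), treatments = "pH7.1",
                         layer = "metaproteome", prefix = "MP")
  mp <- CountTable(matrix(c(40, 3, 0, 0, 20, 1, 0, 0), nrow = 4,
                          dimnames = list(paste0("t", 1:4), metaP$sample_id)),
                   "metaproteome", "taxon", sampleData = metaP)
  pres <- crossLayerPresence(mg, mp)
  d1 <- pres[pres$day == 1, ]
  expect_equal(d1$status[match(c("t1", "t2", "t3", "t4"), d1$feature_id)],
               c("both", "metaproteome_only", "metagenome_only", "neither"))
  # partition identity: both + metagenome_only == taxa with nonzero reads
  expect_equal(sum(d1$status %in% c("both", "metagenome_only")),
               sum(d1$read_count > 0))
})

test_that("per-condition regressions zero-fill features missing in one layer", {
  meta <- conditionMeta(days = c(1, 5), treatments = "pH7.1")
  withr::with_seed(11, {
    m <- matrix(rpois(8, 50) + 1, 4,
                dimnames = list(paste0("t", 1:4), meta$sample_id))
  })
  mg <- CountTable(m, "metagenome", "taxon", sampleData = meta)
  metaP <- conditionMeta(days = c(1, 5), treatments = "pH7.1",
                         layer = "metaproteome", prefix = "MP")
  m2 <- m[1:3, ] * 2
  colnames(m2) <- metaP$sample_id
  mp <- CountTable(m2, "metaproteome", "taxon", sampleData = metaP)
  res <- concordanceByCondition(mg, mp)
  expect_equal(nrow(res), 2L)
  expect_equal(res$n_features, c(4L, 4L))
  expect_true(all(res$r_squared >= 0 & res$r_squared <= 1))
})
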