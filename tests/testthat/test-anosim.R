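test_that("maximal group separation gives R = 1", {
  # two groups of 3: within-group dissimilarities all below between-group
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1
  d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(d, g, nPerm = 99, seed = 1)
  expect_equal(anosimR(res), 1)
})

test_that("R statistic agrees exactly with vegan on random data", {
  withr::with_seed(8, {
    for (i in 1:5) {
      m <- matrix(rpois(15 * 9, 12) + 1, 15, 9,
                  dimnames = list(paste0("f", 1:15), paste0("s", 1:9)))
      g <- rep(c("a", "b", "c"), each = 3)
      d <- brayCurtis(m)
      ref <- vegan::anosim(stats::as.dist(d), g, permutations = 0)
      expect_equal(anosimR(anosim(d, g, nPerm = 19, seed = i)),
                   unname(ref$statistic), tolerance = 1e-12)
    }
  })
})

test_that("Monte-Carlo sampling reproduces the exhaustive permutation test", {
  withr::with_seed(13, {
    m <- matrix(rpois(8 * 6, 10) + 1, 8, 6,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
  })
  d <- brayCurtis(m)
  g <- rep(c("a", "b"), each = 3)
  ex <- anosim(d, g, exhaustive = TRUE)
  nPerm <- 4999
  mc <- anosim(d, g, nPerm = nPerm, seed = 7)
  expect_equal(anosimR(mc), anosimR(ex), tolerance = 1e-12)
  se <- sqrt(anosimP(ex) * (1 - anosimP(ex)) / nPerm)
  expect_lt(abs(anosimP(mc) - anosimP(ex)), 2 * se + 2 / nPerm)
})

test_that("permutation p-values are reproducible and floored", {
  d <- brayCurtis(toyMatrix(nf = 10, ns = 8, seed = 3))
  g <- rep(c("a", "b"), each = 4)
  r1 <- anosim(d, g, nPerm = 199, seed = 5)
  r2 <- anosim(d, g, nPerm = 199, seed = 5)
  expect_identical(anosimP(r1), anosimP(r2))
  expect_gte(anosimP(r1), 1 / 200)
})

test_that("degenerate groupings and malformed matrices are rejected", {
  d <- brayCurtis(toyMatrix(nf = 10, ns = 5, seed = 2))
  expect_error(anosim(d, c("a", "a", "a", "a", "b"), nPerm = 9), "size 1")
  expect_error(anosim(d, rep("a", 5), nPerm = 9), "2 groups")
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(anosim(bad, rep(c("a", "b"), c(2, 3)), nPerm = 9),
               "symmetric")
})
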