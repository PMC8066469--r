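test_that("diversity indices match closed forms and hand evaluations", {
  expect_equal(shannonWeaver(rep(3, 5)), log(5), tolerance = 1e-12)
  expect_equal(shannonWeaver(c(0, 10, 0)), 0)
  # counts (1, 1, 2): -(0.25 ln 0.25 * 2 + 0.5 ln 0.5)
  expect_equal(shannonWeaver(c(1, 1, 2)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_equal(shannonWeaver(c(1, 1, 1, 1), base = 2), 2)

  expect_equal(simpsonReciprocal(rep(7, 4)), 4)
  expect_equal(simpsonReciprocal(c(0, 5)), 1)
  expect_equal(simpsonReciprocal(c(1, 1, 2)), 1 / 0.375)

  expect_error(shannonWeaver(c(0, 0)), "zero")
  expect_error(simpsonReciprocal(numeric(3)), "zero")
})

test_that("diversity indices agree with vegan and are scale invariant", {
  withr::with_seed(21, x <- rpois(30, 8) + rbinom(30, 1, 0.5))
  x <- x[x >= 0]
  expect_equal(shannonWeaver(x), unname(vegan::diversity(x, "shannon")))
  expect_equal(simpsonReciprocal(x), unname(vegan::diversity(x, "invsimpson")))
  expect_equal(shannonWeaver(x * 1000), shannonWeaver(x))
  expect_equal(simpsonReciprocal(x * 0.001), simpsonReciprocal(x))
})

test_that("diversityTable reports both indices per sample and bounds hold", {
  ct <- toyCountTable(nf = 12, ns = 5)
  dv <- diversityTable(ct)
  expect_equal(nrow(dv), 5L)
  k <- nrow(ct)
  expect_true(all(dv$shannon_weaver >= 0 & dv$shannon_weaver <= log(k)))
  expect_true(all(dv$simpson_reciprocal >= 1 & dv$simpson_reciprocal <= k))
})

test_that("Bray-Curtis matches its definition and vegan", {
  same <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2,
                 dimnames = list(paste0("f", 1:3), c("a", "b")))
  expect_equal(brayCurtis(same)["a", "b"], 0)

  disjoint <- matrix(c(1, 0, 0, 2), ncol = 2,
                     dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_equal(brayCurtis(disjoint)["a", "b"], 1)

  hand <- matrix(c(1, 2, 2, 2), ncol = 2,
                 dimnames = list(c("f1", "f2"), c("x", "y")))
  expect_equal(brayCurtis(hand)["x", "y"], 1 / 7)

  m <- toyMatrix(nf = 20, ns = 6, seed = 5)
  d <- brayCurtis(m)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_equal(d, as.matrix(vegan::vegdist(t(m), "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # invariant to feature order
  expect_equal(brayCurtis(m[sample(20), ]), d)

  zz <- matrix(0, 2, 2, dimnames = list(c("f1", "f2"), c("a", "b")))
  expect_error(brayCurtis(zz), "all-zero")
})
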