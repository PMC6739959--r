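test_that("identical blocks are perfectly integrated", {
  set.seed(71)
  Y <- matrix(rnorm(15 * 4), 15, 4)
  r <- twoBlockPls(Y, Y, nperm = 0)
  expect_equal(r@cors[1], 1, tolerance = 1e-12)
})

test_that("r-PLS is invariant to rotations within a block", {
  set.seed(72)
  b <- simulateCorrelatedBlocks(30, 6, 6, rho = 0.7, seed = 1)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))       # random orthogonal matrix
  r1 <- twoBlockPls(b$Y1, b$Y2, nperm = 0)
  r2 <- twoBlockPls(b$Y1, b$Y2 %*% Q, nperm = 0)
  expect_equal(r1@cors[1], r2@cors[1], tolerance = 1e-10)
  expect_equal(r1@singularValues, r2@singularValues, tolerance = 1e-10)
})

test_that("strong integration is detected, scores match loadings", {
  b <- simulateCorrelatedBlocks(50, 8, 8, rho = 0.9, seed = 2)
  r <- twoBlockPls(b$Y1, b$Y2, nperm = 999, seed = 3)
  expect_equal(r@pValue, 0.001)
  expect_gt(r@cors[1], 0.7)
  expect_gt(r@effectSize, 2)
  expect_equal(r@xScores, scale(b$Y1, scale = FALSE) %*% r@xLoadings,
               tolerance = 1e-10)
  expect_equal(length(r@permDist), 999L)
})

test_that("PLS permutations are seed-reproducible and RNG-clean", {
  b <- simulateCorrelatedBlocks(20, 4, 4, rho = 0.5, seed = 4)
  set.seed(73)
  before <- .Random.seed
  r1 <- twoBlockPls(b$Y1, b$Y2, nperm = 199, seed = 5)
  expect_identical(.Random.seed, before)
  r2 <- twoBlockPls(b$Y1, b$Y2, nperm = 199, seed = 5)
  expect_identical(r1@permDist, r2@permDist)
  expect_identical(r1@pValue, r2@pValue)
})

test_that("effect sizes compare as expected", {
  strong <- simulateCorrelatedBlocks(40, 6, 6, rho = 0.95, seed = 6)
  rs <- twoBlockPls(strong$Y1, strong$Y2, nperm = 499, seed = 7)
  expect_equal(unname(plsEffectSize(rs)["z"]), rs@effectSize)
  same <- comparePls(rs, rs)
  expect_equal(same$zDiff, 0)
  expect_equal(same$p, 1)
  weak <- simulateCorrelatedBlocks(40, 6, 6, rho = 0, seed = 8)
  rw <- twoBlockPls(weak$Y1, weak$Y2, nperm = 499, seed = 9)
  cmp <- comparePls(rs, rw)
  expect_lt(cmp$p, 0.05)               # rho 0.95 vs 0 at n = 40 must differ
})

test_that("major-axis slopes are exact on noiseless lines", {
  x <- seq(-2, 2, length.out = 11)
  expect_equal(majorAxisSlope(x, 2 * x + 1), 2, tolerance = 1e-12)
  expect_equal(majorAxisSlope(x, -0.5 * x), -0.5, tolerance = 1e-12)
  # symmetry: swapping the roles inverts the slope
  set.seed(74)
  y <- x + rnorm(11, sd = 0.3)
  expect_equal(majorAxisSlope(x, y) * majorAxisSlope(y, x), 1,
               tolerance = 1e-10)
  expect_equal(majorAxisSlope(x, rep(0, 11)), 0)
  expect_equal(majorAxisSlope(rep(0, 11), x), Inf)
})

test_that("identical groups give p = 1 in slope comparison", {
  set.seed(75)
  x <- rnorm(10); y <- 1.5 * x + rnorm(10, sd = 0.2)
  g <- rep(c("a", "b"), 10)            # interleaved identical halves
  r <- compareMaSlopes(c(x, x), c(y, y), rep(c("a", "b"), each = 10),
                       nperm = 199, seed = 1)
  expect_equal(unname(r$slopes["a"]), unname(r$slopes["b"]))
  expect_equal(r$p[1, 2], 1)
})

test_that("clearly different slopes are detected", {
  set.seed(76)
  x <- rnorm(30)
  y1 <- 2 * x + rnorm(30, sd = 0.1)
  y2 <- -2 * x + rnorm(30, sd = 0.1)
  r <- compareMaSlopes(c(x, x), c(y1, y2), rep(c("a", "b"), each = 30),
                       nperm = 999, seed = 2)
  expect_equal(r$p[1, 2], 0.001)
})

test_that("global-integration slope hits the generative exponent", {
  w <- simulateWarpSample(150, exponent = 1, seed = 77)
  r <- globalIntegrationSlope(w$shapes, w$spectrum)
  expect_lt(abs(r@slope - (-1)), 0.15)
  w2 <- simulateWarpSample(150, exponent = 2, seed = 78)
  r2 <- globalIntegrationSlope(w2$shapes, w2$spectrum)
  expect_lt(r2@slope, -1)
  expect_identical(r2@interpretation, "integrated")
  w0 <- simulateWarpSample(150, exponent = 0, seed = 79)
  r0 <- globalIntegrationSlope(w0$shapes, w0$spectrum)
  expect_gt(r0@slope, -1)
  expect_identical(r0@interpretation, "dis-integrated")
})

test_that("per-coordinate and summed global-integration slopes agree", {
  w <- simulateWarpSample(120, exponent = 1, seed = 80)
  a <- globalIntegrationSlope(w$shapes, w$spectrum)
  b <- globalIntegrationSlope(w$shapes, w$spectrum, perCoordinate = TRUE)
  expect_lt(abs(a@slope - b@slope), 0.2)
  expect_equal(nrow(b@points), 2L * nrow(a@points))
})

test_that("identical samples give p = 1 in global-integration comparison", {
  w <- simulateWarpSample(20, exponent = 1, seed = 81)
  r <- compareGlobalIntegration(w$shapes, w$shapes, w$spectrum, nperm = 99,
                                seed = 3)
  expect_equal(r$diff, 0)
  expect_equal(r$p, 1)
})

test_that("different spectrum exponents are distinguished between groups", {
  a <- simulateWarpSample(60, exponent = 0, seed = 82)
  b <- simulateWarpSample(60, exponent = 2, seed = 83)
  r <- compareGlobalIntegration(a$shapes, b$shapes, a$spectrum, nperm = 199,
                                seed = 4)
  expect_gt(r$diff, 0.5)
  expect_lte(r$p, 0.01)
})
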