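test_that("centroid size matches its definition", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  # centroid (1,1); four corners each at squared distance 2
  expect_equal(centroidSize(sq), sqrt(8))
  expect_equal(centroidSize(sq * 3), 3 * centroidSize(sq))
  expect_equal(centroidSize(sweep(sq, 2, c(5, -2), "+")), centroidSize(sq))
})

test_that("Procrustes distance is zero across similarity transforms", {
  a <- randShape(8, 1)
  b <- 2.3 * rot2(a, 0.7) + matrix(rep(c(4, -1), each = 8), 8, 2)
  expect_lt(procrustesDistance(a, b), 1e-12)
})

test_that("reflection is rejected unless allowed", {
  a <- randShape(8, 2)
  m <- a %*% diag(c(-1, 1))          # mirrored copy
  expect_gt(procrustesDistance(a, m), 0.1)
  expect_lt(procrustesDistance(a, m, allowReflection = TRUE), 1e-12)
})

test_that("optimal rotation matches a brute-force grid search", {
  a <- randShape(7, 3)
  b <- randShape(7, 4)
  d <- procrustesDistance(a, b)
  dGrid <- gridProcrustesDistance(a, b)
  expect_lt(abs(d - dGrid), 1e-6)
  expect_lte(d, dGrid + 1e-12)        # analytic optimum can only be better
})

test_that("alignOptimal returns the minimizing superimposition", {
  a <- randShape(6, 5)
  b <- randShape(6, 6)
  al <- alignOptimal(a, b)
  pre <- function(m) { m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2)) }
  expect_equal(sqrt(sum((al$aligned - pre(b))^2)), al$distance,
               tolerance = 1e-12)
  # no rotation improves on the returned fit
  for (th in seq(-0.1, 0.1, by = 0.01))
    expect_gte(sqrt(sum((rot2(al$aligned, th) - pre(b))^2)),
               al$distance - 1e-12)
})

test_that("GPA recovers a common shape from similarity copies", {
  base <- randShape(10, 7)
  a <- jitteredCopies(base, 12, seed = 8, noise = 0)
  g <- gpa(a)
  expect_true(g@converged)
  expect_equal(centroidSize(consensusShape(g)), 1, tolerance = 1e-10)
  spread <- apply(coords(g), 3, function(s)
    sqrt(sum((s - consensusShape(g))^2)))
  expect_lt(max(spread), 1e-8)
  # original sizes are preserved in the result
  expect_equal(centroidSizes(g), apply(a, 3, centroidSize))
})

test_that("GPA objective decreases monotonically", {
  base <- randShape(9, 9)
  a <- jitteredCopies(base, 15, seed = 10, noise = 0.05)
  g <- gpa(a)
  expect_true(g@converged)
  expect_true(all(diff(g@history) <= 1e-12))
})

test_that("the GPA consensus is a local optimum", {
  base <- randShape(6, 11)
  a <- jitteredCopies(base, 8, seed = 12, noise = 0.05)
  g <- gpa(a)
  obj <- function(cons) {
    cons <- sweep(cons, 2, colMeans(cons))
    cons <- cons / sqrt(sum(cons^2))
    sum(apply(coords(g), 3, function(s) procrustesDistance(s, cons)^2))
  }
  base0 <- obj(consensusShape(g))
  set.seed(13)
  for (i in 1:10) {
    pert <- consensusShape(g) + matrix(rnorm(12, sd = 0.01), 6, 2)
    expect_gte(obj(pert), base0 - 1e-10)
  }
})

test_that("GPA output is invariant to similarity transforms of the input", {
  base <- randShape(8, 14)
  a <- jitteredCopies(base, 6, seed = 15, noise = 0.05)
  b <- a
  for (i in seq_len(dim(a)[3]))
    b[, , i] <- 1.7 * rot2(a[, , i], 0.4) + matrix(rep(c(2, 3), each = 8), 8, 2)
  g1 <- gpa(a)
  g2 <- gpa(b)
  # GPA output is defined up to a common rotation: compare in shape space
  expect_lt(procrustesDistance(consensusShape(g1), consensusShape(g2)),
            1e-8)
  for (i in seq_len(dim(a)[3]))
    expect_lt(procrustesDistance(coords(g1)[, , i], coords(g2)[, , i]),
              1e-8)
  expect_equal(centroidSizes(g2), 1.7 * centroidSizes(g1), tolerance = 1e-8)
})

test_that("BEN sliding reduces bending energy, PRD reduces distance", {
  tpl <- makeTemplate("humerus36")
  set.seed(16)
  n <- 10
  a <- array(0, dim = c(36, 2, n))
  for (i in seq_len(n))
    a[, , i] <- tpl$template + matrix(rnorm(72, sd = 0.01), 36, 2)
  g0 <- gpa(a)
  gBen <- gpa(a, sliders = tpl$sliders, method = "BEN")
  gPrd <- gpa(a, sliders = tpl$sliders, method = "PRD")
  be <- function(g) mean(apply(coords(g), 3, function(s)
    bendingEnergy(fitTps(consensusShape(g), s))))
  d2 <- function(g) mean(apply(coords(g), 3, function(s)
    sum((s - consensusShape(g))^2)))
  expect_lt(be(gBen), be(g0))
  expect_lt(d2(gPrd), d2(g0))
  expect_lte(be(gBen), be(gPrd) + 1e-12)
  expect_identical(gBen@slidingMethod, "BEN")
})

test_that("sliding moves only the designated semilandmarks", {
  tpl <- makeTemplate("humerus36")
  set.seed(17)
  a <- array(0, dim = c(36, 2, 4))
  for (i in 1:4)
    a[, , i] <- tpl$template + matrix(rnorm(72, sd = 0.01), 36, 2)
  g0 <- gpa(a)
  slid <- slideSemilandmarks(coords(g0), consensusShape(g0), tpl$sliders,
                             method = "BEN", reAlign = FALSE)
  fixed <- setdiff(1:36, tpl$sliders$slider)
  expect_equal(slid[fixed, , ], coords(g0)[fixed, , ])
  expect_gt(sum(abs(slid[tpl$sliders$slider, , ] -
                    coords(g0)[tpl$sliders$slider, , ])), 0)
})

test_that("measurement error requires exactly three replicate sets", {
  cfg <- generatorConfig(nSpecies = 5, sampleSizes = "balanced",
                         nPerSpecies = 2, replicateNoiseSd = 1e-3, seed = 4)
  sim <- simulateSpeciesShapes(cfg)
  sp <- simulateSpecimens(sim$humerus$means, cfg, sim$species)
  expect_error(measurementError(sp$replicates[1:2]), "3|three")
  err <- measurementError(sp$replicates)
  expect_gt(err, 0)
  expect_lt(err, 100)
})

test_that("measurement error grows with replicate noise", {
  errAt <- function(sd) {
    cfg <- generatorConfig(nSpecies = 5, sampleSizes = "balanced",
                           nPerSpecies = 2, replicateNoiseSd = sd, seed = 4)
    sim <- simulateSpeciesShapes(cfg)
    sp <- simulateSpecimens(sim$humerus$means, cfg, sim$species)
    measurementError(sp$replicates)
  }
  expect_lt(errAt(5e-5), errAt(2e-3))
})
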