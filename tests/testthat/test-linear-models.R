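test_that("univariate RRPP F statistics equal closed-form ANOVA", {
  set.seed(51)
  n <- 24
  dat <- data.frame(x = rnorm(n), g = factor(rep(c("a", "b", "c"), each = 8)))
  y <- 0.5 * dat$x + as.numeric(dat$g) + rnorm(n)
  fit <- rrppModel(matrix(y), ~ x + g, dat, nperm = 99, seed = 1)
  ref <- anova(lm(y ~ x + g, dat))
  tab <- anovaTable(fit)
  expect_lt(max(abs(tab$F[1:2] - ref$`F value`[1:2])), 1e-9)
  expect_lt(max(abs(tab$SS[1:2] - ref$`Sum Sq`[1:2])), 1e-9)
  expect_equal(tab$Df[1:2], ref$Df[1:2])
  expect_equal(tab$SS[3], ref$`Sum Sq`[3], tolerance = 1e-12)
})

test_that("ANOVA table bookkeeping is consistent", {
  set.seed(52)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  dat <- data.frame(g = factor(rep(c("a", "b"), each = 15)))
  tab <- anovaTable(rrppModel(Y, ~ g, dat, nperm = 99, seed = 2))
  expect_equal(tab$term, c("g", "Residuals", "Total"))
  expect_equal(sum(tab$SS[1:2]), tab$SS[3], tolerance = 1e-10)
  expect_equal(sum(tab$Df[1:2]), tab$Df[3])
  expect_equal(sum(tab$Rsq[1:2]), 1, tolerance = 1e-10)
})

test_that("a strong group effect is maximally significant", {
  set.seed(53)
  Y <- rbind(matrix(rnorm(10 * 3), 10, 3),
             matrix(rnorm(10 * 3, mean = 5), 10, 3))
  g <- rep(c("a", "b"), each = 10)
  fit <- procrustesAnova(Y, g, nperm = 999, seed = 3)
  expect_equal(anovaTable(fit)$P[1], 0.001)
  expect_gt(anovaTable(fit)$Z[1], 2)
})

test_that("permutations are reproducible by seed", {
  set.seed(54)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  g <- rep(c("a", "b"), each = 10)
  f1 <- procrustesAnova(Y, g, nperm = 199, seed = 9)
  f2 <- procrustesAnova(Y, g, nperm = 199, seed = 9)
  expect_identical(anovaTable(f1), anovaTable(f2))
})

test_that("the permutation stream does not disturb the global RNG", {
  set.seed(55)
  Y <- matrix(rnorm(20 * 2), 20, 2)
  before <- .Random.seed
  invisible(procrustesAnova(Y, rep(c("a", "b"), each = 10),
                            nperm = 99, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("aliased terms are rejected with a named error", {
  set.seed(56)
  dat <- data.frame(g = factor(rep(c("a", "b"), each = 6)))
  dat$h <- dat$g                       # perfectly aliased copy
  Y <- matrix(rnorm(12 * 2), 12, 2)
  expect_error(rrppModel(Y, ~ g + h, dat, nperm = 99), "aliased.*h|h.*aliased")
})

test_that("evolutionaryAllometry fits size, group and their interaction", {
  set.seed(57)
  n <- 40
  cs <- rlnorm(n, log(10), 0.3)
  g <- rep(c("a", "b"), each = 20)
  dir <- c(1, -1, 0.5)
  Y <- outer(scale(cs)[, 1], dir) + matrix(rnorm(n * 3, sd = 0.2), n, 3)
  fit <- evolutionaryAllometry(Y, cs, g, nperm = 199, seed = 4)
  tab <- anovaTable(fit)
  expect_equal(tab$term[1:3], c("size", "group", "size:group"))
  expect_lte(tab$P[1], 0.01)           # strong allometry
  expect_error(evolutionaryAllometry(Y, rep(1, n), g), "constant")
  expect_error(evolutionaryAllometry(Y, -cs, g), "positive")
})

test_that("sizeCorrect removes all linear size association", {
  set.seed(58)
  n <- 30
  cs <- rlnorm(n, log(5), 0.4)
  Y <- outer(cs, c(2, -1)) + matrix(rnorm(n * 2), n, 2)
  Yc <- sizeCorrect(Y, cs)
  expect_lt(max(abs(cov(Yc, cs))), 1e-10)
  expect_equal(colMeans(Yc), colMeans(Y), tolerance = 1e-10)
  # container round-trip: AlignedShapes in, AlignedShapes out
  a <- jitteredCopies(randShape(6, 59), 8, seed = 60, noise = 0.02)
  al <- gpa(a)
  alc <- sizeCorrect(al, centroidSizes(al))
  expect_s4_class(alc, "AlignedShapes")
  expect_equal(dim(coords(alc)), dim(coords(al)))
})

test_that("Procrustes variances match their algebraic definition", {
  set.seed(61)
  Y <- rbind(matrix(rnorm(12 * 3, sd = 1), 12, 3),
             matrix(rnorm(12 * 3, sd = 3), 12, 3))
  g <- rep(c("a", "b"), each = 12)
  d <- morphologicalDisparity(Y, g, nperm = 99, seed = 5)
  for (l in c("a", "b")) {
    R <- scale(Y[g == l, ], scale = FALSE)
    expect_equal(unname(d@variances[l]), sum(R^2) / 12, tolerance = 1e-12)
  }
  expect_equal(d@pairwiseDiff[1, 2],
               unname(abs(d@variances["a"] - d@variances["b"])),
               tolerance = 1e-12)
  expect_lte(d@pairwiseP[1, 2], 0.05)  # 9x variance ratio must be detected
})

test_that("disparity of a group against its own copy is never significant", {
  set.seed(62)
  Y1 <- matrix(rnorm(10 * 3), 10, 3)
  Y <- rbind(Y1, Y1)
  g <- rep(c("a", "b"), each = 10)
  d <- morphologicalDisparity(Y, g, nperm = 199, seed = 6)
  expect_equal(d@pairwiseDiff[1, 2], 0)
  expect_equal(d@pairwiseP[1, 2], 1)
})

test_that("covariate adjustment removes size-driven disparity", {
  set.seed(63)
  n <- 40
  g <- rep(c("a", "b"), each = 20)
  cs <- c(rlnorm(20, 0, 0.1), rlnorm(20, 0, 1))   # b varies far more in size
  Y <- outer(log(cs), c(1, 1, 1)) + matrix(rnorm(n * 3, sd = 0.1), n, 3)
  raw <- morphologicalDisparity(Y, g, nperm = 99, seed = 7)
  adj <- morphologicalDisparity(Y, g, covariate = log(cs), nperm = 99,
                                seed = 7)
  expect_gt(raw@variances["b"] / raw@variances["a"], 10)
  expect_lt(adj@variances["b"] / adj@variances["a"],
            raw@variances["b"] / raw@variances["a"] / 10)
})
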