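test_that("TPS interpolates the source landmarks exactly", {
  src <- randShape(9, 21)
  tgt <- src + matrix(rnorm(18, sd = 0.1), 9, 2)
  m <- fitTps(src, tgt)
  expect_equal(evaluateTps(m, src), tgt, tolerance = 1e-10)
})

test_that("affine maps have zero bending energy", {
  src <- randShape(8, 22)
  A <- matrix(c(1.2, 0.1, -0.3, 0.9), 2, 2)
  tgt <- src %*% t(A) + matrix(rep(c(0.5, -1), each = 8), 8, 2)
  m <- fitTps(src, tgt)
  expect_lt(bendingEnergy(m), 1e-20)
  expect_lt(max(abs(m@weights)), 1e-10)
})

test_that("bending energy is quadratically homogeneous", {
  src <- randShape(10, 23)
  d <- matrix(rnorm(20, sd = 0.05), 10, 2)
  b1 <- bendingEnergy(fitTps(src, src + d))
  b4 <- bendingEnergy(fitTps(src, src + 4 * d))
  expect_equal(b4, 16 * b1, tolerance = 1e-8)
  expect_gt(b1, 0)
})

test_that("bending spectrum has k-3 positive eigenvalues and an orthonormal
           non-affine basis", {
  ref <- makeTemplate("humerus36")$template
  sp <- bendingSpectrum(ref)
  k <- nrow(ref)
  expect_length(sp@values, k - 3L)
  expect_true(all(sp@values > 0))
  expect_true(all(diff(sp@values) >= 0))          # ascending
  V <- sp@vectors
  expect_equal(crossprod(V), diag(k - 3L), tolerance = 1e-10)
  # orthogonal to the affine null space (1, x, y)
  aff <- cbind(1, ref)
  expect_lt(max(abs(crossprod(aff, V))), 1e-8)
})

test_that("partial warp scores satisfy the Parseval identity", {
  tpl <- makeTemplate("humerus36")
  sp <- bendingSpectrum(tpl$template)
  set.seed(24)
  n <- 40
  m <- length(sp@values)
  a <- array(0, dim = c(36, 2, n))
  for (i in seq_len(n)) {
    dx <- sp@vectors %*% rnorm(m, sd = 0.01)
    dy <- sp@vectors %*% rnorm(m, sd = 0.01)
    a[, , i] <- tpl$template + cbind(dx, dy)
  }
  sc <- partialWarpScores(a, sp)
  totalWarpVar <- sum(apply(sc[, , 1], 2, var)) + sum(apply(sc[, , 2], 2, var))
  devs <- t(apply(a, 3, c))
  totalVar <- sum(apply(devs, 2, var))
  expect_lt(abs(totalWarpVar - totalVar), 1e-9)
})

test_that("the analytic Jacobian matches numeric differentiation", {
  src <- randShape(8, 25)
  tgt <- src + matrix(rnorm(16, sd = 0.08), 8, 2)
  m <- fitTps(src, tgt)
  pts <- randShape(12, 26) * 0.8
  ld <- jacobianLogDetField(m, pts)
  eps <- 1e-6
  num <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, , drop = FALSE]
    fx <- (evaluateTps(m, p + c(eps, 0)) - evaluateTps(m, p - c(eps, 0))) /
      (2 * eps)
    fy <- (evaluateTps(m, p + c(0, eps)) - evaluateTps(m, p - c(0, eps))) /
      (2 * eps)
    J <- rbind(fx, fy)             # rows: d/dx, d/dy of (u, v)
    log(abs(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]))
  }, numeric(1))
  expect_lt(max(abs(ld - num)), 1e-5)
})

test_that("uniform scaling has a constant log-Jacobian of log(scale^2)", {
  src <- randShape(7, 27)
  m <- fitTps(src, 2 * src)
  pts <- randShape(9, 28)
  expect_equal(jacobianLogDetField(m, pts), rep(log(4), 9),
               tolerance = 1e-10)
  mId <- fitTps(src, src)
  expect_equal(jacobianLogDetField(mId, pts), rep(0, 9), tolerance = 1e-10)
})

test_that("folded maps yield NaN log-Jacobians with a warning", {
  src <- randShape(7, 29)
  m <- fitTps(src, src %*% diag(c(-1, 1)))   # reflection: negative Jacobian
  expect_warning(ld <- jacobianLogDetField(m, randShape(5, 30)),
                 "fold|negative")
  expect_true(all(is.nan(ld)))
})

test_that("deformation grids cover the reference with the requested density", {
  ref <- makeTemplate("mandible38")$template
  g <- makeEvaluationGrid(ref, n = 10, expand = 0.05)
  expect_equal(nrow(g), 100L)
  expect_true(all(g[, 1] <= max(ref[, 1]) + 0.2 * diff(range(ref[, 1]))))
  set.seed(31)
  m <- fitTps(ref, ref + matrix(rnorm(76, sd = 0.005), 38, 2))
  df <- deformationField(m, n = 10)
  expect_named(df, c("x", "y", "logdet"))
  expect_equal(nrow(df), 100L)
  expect_true(all(is.finite(df$logdet)))
})
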