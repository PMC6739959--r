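# Thin-plate splines with the Bookstein kernel U(r) = r^2 log(r^2).

.tpsU <- function(r2) ifelse(r2 > 0, r2 * log(r2), 0)

.tpsK <- function(src) {
  d2 <- as.matrix(stats::dist(src))^2
  .tpsU(d2)
}

# k x k bending-energy matrix at a reference: the upper-left block of the
# inverse of the bordered TPS system matrix.
.bendingEnergyMatrix <- function(ref) {
  k <- nrow(ref)
  if (k < 4L) stop("at least 4 landmarks required")
  K <- .tpsK(ref)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("degenerate reference: collinear or duplicated points"))
  Be <- Li[seq_len(k), seq_len(k)]
  (Be + t(Be)) / 2
}

#' Fit a thin-plate-spline map between two configurations
#'
#' Solves the standard TPS linear system with kernel U(r) = r^2 log(r^2); the
#' resulting map interpolates every source landmark exactly onto its target.
#'
#' @param source,target \code{k x 2} matrices, equal k >= 4; the source must
#'   not be collinear or contain duplicated points.
#' @return a \linkS4class{TpsModel}.
#' @export
fitTps <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    stop("source and target must have equal dimensions")
  k <- nrow(source)
  if (k < 4L) stop("at least 4 landmarks required")
  K <- .tpsK(source)
  Q <- cbind(1, source)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop("degenerate reference: collinear or duplicated source points"))
  new("TpsModel", source = source, target = target,
      affine = coef[k + 1:3, , drop = FALSE],
      weights = coef[seq_len(k), , drop = FALSE])
}

#' Evaluate a TPS model at arbitrary points
#'
#' @param model a \linkS4class{TpsModel}.
#' @param points \code{m x 2} matrix of evaluation points.
#' @return \code{m x 2} matrix of mapped points.
#' @export
evaluateTps <- function(model, points) {
  points <- matrix(points, ncol = 2)
  dx <- outer(points[, 1], model@source[, 1], "-")
  dy <- outer(points[, 2], model@source[, 2], "-")
  U <- .tpsU(dx^2 + dy^2)
  cbind(1, points) %*% model@affine + U %*% model@weights
}

#' Bending energy of a TPS model
#'
#' The standard quadratic form (weights' K weights, summed over the x and y
#' coordinates); zero iff the map is affine. Quadratically homogeneous in the
#' landmark displacements.
#'
#' @param model a \linkS4class{TpsModel}.
#' @return a non-negative number.
#' @export
bendingEnergy <- function(model) {
  K <- .tpsK(model@source)
  max(0, sum(model@weights * (K %*% model@weights)))
}

#' Bending-energy spectrum (partial warps) of a reference shape
#'
#' Eigendecomposition of the k x k bending-energy matrix computed at the
#' reference; the three numerically zero eigenvalues (the affine kernel) are
#' discarded and the k - 3 positive eigenvalues are returned in ascending
#' order with their orthonormal eigenvectors, the partial-warp directions.
#'
#' @param reference a non-degenerate \code{k x 2} configuration, typically a
#'   GPA consensus.
#' @return a \linkS4class{BendingSpectrum}.
#' @export
bendingSpectrum <- function(reference) {
  reference <- as.matrix(reference)
  k <- nrow(reference)
  Be <- .bendingEnergyMatrix(reference)
  e <- eigen(Be, symmetric = TRUE)
  keep <- seq_len(k - 3L)           # eigen() returns descending order
  vals <- e$values[keep]
  if (any(vals <= 0) || max(abs(e$values[-keep])) > 1e-8 * max(vals))
    stop("degenerate reference: bending spectrum lacks exactly 3 zero modes")
  ord <- rev(keep)
  new("BendingSpectrum", values = vals[ord],
      vectors = e$vectors[, keep, drop = FALSE][, ord, drop = FALSE],
      reference = reference)
}

#' Partial-warp scores of an aligned sample
#'
#' Projects each specimen's residual from the reference onto each
#' partial-warp direction, separately for the x and y coordinates. The
#' affine (uniform) component of shape variation lies in the discarded
#' zero-eigenvalue subspace and does not contribute; total non-affine
#' variance equals the summed per-warp score variances (Parseval identity).
#'
#' @param sample an \linkS4class{AlignedShapes} (aligned to the spectrum's
#'   reference) or a \code{k x 2 x n} array.
#' @param spectrum a \linkS4class{BendingSpectrum}.
#' @return an \code{n x (k-3) x 2} score array.
#' @export
partialWarpScores <- function(sample, spectrum) {
  a <- if (is(sample, "AlignedShapes")) sample@coords else sample
  k <- dim(a)[1]
  if (k != nrow(spectrum@reference))
    stop("reference mismatch: sample and spectrum landmark counts differ")
  n <- dim(a)[3]
  V <- spectrum@vectors
  sc <- array(0, dim = c(n, ncol(V), 2L),
              dimnames = list(dimnames(a)[[3]], NULL, c("x", "y")))
  for (i in seq_len(n)) {
    r <- a[, , i] - spectrum@reference
    sc[i, , 1] <- crossprod(V, r[, 1])
    sc[i, , 2] <- crossprod(V, r[, 2])
  }
  sc
}

#' Analytic Jacobian log-determinant field of a TPS map
#'
#' Computes the 2 x 2 Jacobian of the TPS map analytically (affine part plus
#' kernel derivative terms, with the r -> 0 limit of the gradient set to 0)
#' and returns log(det J) per evaluation point: values below 0 indicate local
#' area reduction relative to the source, values above 0 enlargement. Points
#' where the map folds (det J <= 0) are returned as NaN with a warning.
#'
#' @param model a \linkS4class{TpsModel}.
#' @param grid \code{m x 2} matrix of evaluation points.
#' @return numeric vector of length m.
#' @export
jacobianLogDetField <- function(model, grid) {
  grid <- matrix(grid, ncol = 2)
  dx <- outer(grid[, 1], model@source[, 1], "-")
  dy <- outer(grid[, 2], model@source[, 2], "-")
  r2 <- dx^2 + dy^2
  g <- ifelse(r2 > 0, log(r2) + 1, 0)   # dU/d(dx) = 2 dx (log r^2 + 1)
  gx <- 2 * dx * g
  gy <- 2 * dy * g
  w <- model@weights
  j11 <- model@affine[2, 1] + gx %*% w[, 1]
  j12 <- model@affine[3, 1] + gy %*% w[, 1]
  j21 <- model@affine[2, 2] + gx %*% w[, 2]
  j22 <- model@affine[3, 2] + gy %*% w[, 2]
  det <- as.numeric(j11 * j22 - j12 * j21)
  out <- ifelse(det > 0, log(pmax(det, .Machine$double.xmin)), NaN)
  if (anyNA(out)) warning("folded map: det J <= 0 at ",
                          sum(is.na(out)), " point(s)")
  out
}

#' Regular evaluation grid over a reference shape
#'
#' A \code{n x n} grid spanning the reference bounding box expanded by a
#' fraction on each side, for deformation-field visualization.
#'
#' @param reference \code{k x 2} configuration.
#' @param n grid points per side.
#' @param expand fractional bounding-box expansion.
#' @return \code{n^2 x 2} matrix of grid points.
#' @export
makeEvaluationGrid <- function(reference, n = 24, expand = 0.05) {
  rx <- range(reference[, 1]); ry <- range(reference[, 2])
  ex <- diff(rx) * expand; ey <- diff(ry) * expand
  gx <- seq(rx[1] - ex, rx[2] + ex, length.out = n)
  gy <- seq(ry[1] - ey, ry[2] + ey, length.out = n)
  as.matrix(expand.grid(x = gx, y = gy))
}

#' Jacobian field as an exportable table
#'
#' @inheritParams jacobianLogDetField
#' @param n,expand grid parameters, see [makeEvaluationGrid()].
#' @return data.frame with columns \code{x}, \code{y}, \code{logdet}.
#' @export
deformationField <- function(model, n = 24, expand = 0.05) {
  g <- makeEvaluationGrid(model@source, n = n, expand = expand)
  data.frame(x = g[, 1], y = g[, 2],
             logdet = jacobianLogDetField(model, g))
}
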