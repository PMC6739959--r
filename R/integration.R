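# Two-block partial least squares, integration effect sizes, major-axis
# comparisons, and Bookstein's global-integration regression.

.atanhSafe <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

.plsCore <- function(Y1, Y2, center = TRUE) {
  if (center) { Y1 <- .center(Y1); Y2 <- .center(Y2) }
  S12 <- crossprod(Y1, Y2) / (nrow(Y1) - 1)
  sv <- svd(S12)
  list(Y1 = Y1, Y2 = Y2, sv = sv)
}

.plsFirstR <- function(Y1, Y2, center = TRUE) {
  cc <- .plsCore(Y1, Y2, center)
  stats::cor(cc$Y1 %*% cc$sv$u[, 1], cc$Y2 %*% cc$sv$v[, 1])
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-covariance matrix between two
#' blocks of variables measured on the same specimens. The integration
#' statistic r-PLS is the Pearson correlation of the first paired scores;
#' its significance is assessed by permuting the rows of the second block
#' and recomputing the full statistic.
#'
#' @param Y1,Y2 \code{n x p1} and \code{n x p2} matrices, same n >= 3;
#'   columns are centered internally.
#' @param nperm number of permutations (0 skips inference).
#' @param seed integer seed.
#' @param center center the blocks (disabled by the phylogenetic wrapper,
#'   which centers on the phylogenetic mean instead).
#' @return a \linkS4class{PlsResult}. Axis-1 scores are oriented so their
#'   correlation is non-negative; loadings have their largest element
#'   positive.
#' @export
twoBlockPls <- function(Y1, Y2, nperm = 999, seed = NULL, center = TRUE) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  n <- nrow(Y1)
  if (nrow(Y2) != n) stop("blocks must have the same number of rows")
  if (n < 3L) stop("at least 3 specimens required")
  if (all(apply(Y1, 2, stats::var) == 0) ||
      all(apply(Y2, 2, stats::var) == 0))
    stop("zero-variance block")
  cc <- .plsCore(Y1, Y2, center)
  U <- cc$sv$u; V <- cc$sv$v
  for (j in seq_len(ncol(U))) {       # deterministic sign convention
    if (U[which.max(abs(U[, j])), j] < 0) {
      U[, j] <- -U[, j]; V[, j] <- -V[, j]
    }
  }
  xs <- cc$Y1 %*% U
  ys <- cc$Y2 %*% V
  cors <- vapply(seq_len(ncol(xs)), function(j) {
    if (stats::sd(xs[, j]) == 0 || stats::sd(ys[, j]) == 0) return(NA_real_)
    stats::cor(xs[, j], ys[, j])
  }, numeric(1))
  if (isTRUE(cors[1] < 0)) {          # orient axis 1 positively
    V[, 1] <- -V[, 1]; ys[, 1] <- -ys[, 1]; cors[1] <- -cors[1]
  }
  pd <- numeric(0); p <- NA_real_; z <- NA_real_; se <- NA_real_
  if (nperm > 0) {
    perms <- .permIndices(n, nperm, seed)
    pd <- vapply(seq_len(nperm), function(b)
      abs(.plsFirstR(cc$Y1, cc$Y2[perms[b, ], , drop = FALSE],
                     center = FALSE)), numeric(1))
    p <- .permP(cors[1], pd)
    fp <- .atanhSafe(pd)
    s <- stats::sd(fp)
    if (s > 0) {
      z <- (.atanhSafe(cors[1]) - mean(fp)) / s
      se <- stats::sd((fp - mean(fp)) / s)
    }
  }
  new("PlsResult", singularValues = cc$sv$d, xScores = xs, yScores = ys,
      xLoadings = U, yLoadings = V, cors = cors, pValue = p, permDist = pd,
      effectSize = z, effectSizeSE = se, nperm = nperm)
}

#' Standardized integration effect size of a PLS result
#'
#' The z-score of the observed r-PLS against its permutation distribution
#' after Fisher's arctanh variance stabilization, with a standard error
#' estimated from the same distribution. Allows two-sample comparisons of
#' integration strength via [comparePls()].
#'
#' @param result a \linkS4class{PlsResult} carrying a permutation
#'   distribution (nperm >= 99).
#' @return named vector \code{c(z, se)}.
#' @export
plsEffectSize <- function(result) {
  if (length(result@permDist) < 99)
    stop("permutation distribution with nperm >= 99 required")
  fp <- .atanhSafe(result@permDist)
  s <- stats::sd(fp)
  if (s == 0) stop("degenerate permutation distribution (sd = 0)")
  z <- (.atanhSafe(result@cors[1]) - mean(fp)) / s
  c(z = z, se = stats::sd((fp - mean(fp)) / s))
}

#' Two-sample comparison of integration effect sizes
#'
#' Two-sample z-test on standardized PLS effect sizes using the pooled
#' standard error from the two sampling (permutation) distributions.
#'
#' @param a,b \linkS4class{PlsResult} objects with effect sizes.
#' @return list with \code{zDiff} and the two-sided normal \code{p}.
#' @export
comparePls <- function(a, b) {
  if (!is.finite(a@effectSize) || !is.finite(b@effectSize) ||
      !is.finite(a@effectSizeSE) || !is.finite(b@effectSizeSE))
    stop("both results must carry effect sizes and standard errors")
  zd <- (a@effectSize - b@effectSize) /
    sqrt(a@effectSizeSE^2 + b@effectSizeSE^2)
  list(zDiff = zd, p = 2 * stats::pnorm(-abs(zd)))
}

#' Major-axis regression slope
#'
#' Symmetric line fit minimizing orthogonal residuals (the first principal
#' axis of the 2D covariance matrix), appropriate when neither score block
#' is the dependent variable.
#'
#' @param x,y numeric vectors, n >= 3, not all points identical.
#' @return the major-axis slope; when the covariance is exactly zero the
#'   slope is 0 if x carries at least as much variance as y and Inf
#'   (vertical) otherwise.
#' @export
majorAxisSlope <- function(x, y) {
  if (length(x) < 3L) stop("at least 3 points required")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 && syy == 0) stop("zero variance in both coordinates")
  if (sxy == 0) return(if (sxx >= syy) 0 else Inf)
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

#' Pairwise permutation comparison of major-axis slopes
#'
#' Per group pair, the statistic is the angle between the two major-axis
#' LINES (axial difference: arctangent differences are folded into
#' \code{[0, pi/2]}, so a slope of +89 degrees and one of -89 degrees are
#' correctly treated as nearly identical lines); the null is built by
#' permuting group labels over specimens. Ties count as at least as extreme,
#' so identical groups give p = 1.
#'
#' @param x,y score vectors (e.g. first-pair PLS scores).
#' @param groups group labels, each group n >= 3.
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return list with per-group \code{slopes}, pairwise \code{angleDiff} and
#'   \code{p} matrices.
#' @export
compareMaSlopes <- function(x, y, groups, nperm = 999, seed = NULL) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) < 2L) stop("at least 2 groups required")
  if (any(table(groups) < 3L)) stop("every group needs at least 3 points")
  slopes <- vapply(lv, function(l)
    majorAxisSlope(x[groups == l], y[groups == l]), numeric(1))
  ng <- length(lv)
  axialDiff <- function(ang) {
    d <- abs(outer(ang, ang, "-"))
    pmin(d, pi - d)                    # lines are axial: fold to [0, pi/2]
  }
  obs <- axialDiff(atan(slopes))
  perms <- .permIndices(length(x), nperm, seed)
  cnt <- matrix(0, ng, ng)
  for (b in seq_len(nperm)) {
    gb <- groups[perms[b, ]]
    ab <- atan(vapply(lv, function(l)
      majorAxisSlope(x[gb == l], y[gb == l]), numeric(1)))
    cnt <- cnt + (axialDiff(ab) >= obs - 1e-12)
  }
  p <- (cnt + 1) / (nperm + 1)
  diag(p) <- NA
  dimnames(obs) <- dimnames(p) <- list(lv, lv)
  list(slopes = slopes, angleDiff = obs, p = p)
}

# log-log points of the global-integration regression for a shape array.
.giPoints <- function(a, spectrum, perCoordinate = FALSE) {
  sc <- partialWarpScores(a, spectrum)
  if (perCoordinate) {
    v <- rbind(apply(sc[, , 1, drop = FALSE], 2, stats::var),
               apply(sc[, , 2, drop = FALSE], 2, stats::var))
    lam <- rep(spectrum@values, each = 2)
    v <- as.numeric(v)
  } else {
    v <- apply(sc[, , 1, drop = FALSE], 2, stats::var) +
         apply(sc[, , 2, drop = FALSE], 2, stats::var)
    lam <- spectrum@values
  }
  keep <- v > 0
  if (!all(keep)) warning("dropping ", sum(!keep),
                          " zero-variance partial warp(s)")
  data.frame(logLambda = log(lam[keep]), logVariance = log(v[keep]))
}

.giSlope <- function(a, spectrum, perCoordinate = FALSE) {
  pts <- .giPoints(a, spectrum, perCoordinate)
  stats::coef(stats::lm(logVariance ~ logLambda, pts))
}

#' Global (intrinsic) integration regression
#'
#' Ordinary least-squares regression of log partial-warp variance on log
#' bending energy (the eigenvalues of the bending-energy matrix at the
#' consensus). A slope of exactly -1 corresponds to self-similar variation
#' (no interpretable change at any spatial scale); slopes below -1 indicate
#' integration, slopes above -1 dis-integration.
#'
#' @param sample an \linkS4class{AlignedShapes} or \code{k x 2 x n} array
#'   (n >= 3) aligned to the spectrum's reference.
#' @param spectrum a \linkS4class{BendingSpectrum} with >= 2 positive
#'   eigenvalues (k >= 5).
#' @param perCoordinate regress the x and y warp variances as separate
#'   points instead of their sum (one point per warp is the default).
#' @param selfSimTol half-width of the band around -1 declared
#'   "self-similar".
#' @return a \linkS4class{GlobalIntegrationResult}.
#' @export
globalIntegrationSlope <- function(sample, spectrum, perCoordinate = FALSE,
                                   selfSimTol = 0.05) {
  a <- if (is(sample, "AlignedShapes")) sample@coords else sample
  if (length(spectrum@values) < 2L)
    stop("need at least 2 positive bending eigenvalues (k >= 5)")
  if (dim(a)[3] < 3L) stop("at least 3 specimens required")
  pts <- .giPoints(a, spectrum, perCoordinate)
  cf <- stats::coef(stats::lm(logVariance ~ logLambda, pts))
  slope <- unname(cf[2])
  interp <- if (slope < -1 - selfSimTol) "integrated"
            else if (slope > -1 + selfSimTol) "dis-integrated"
            else "self-similar"
  new("GlobalIntegrationResult", slope = slope, intercept = unname(cf[1]),
      points = pts, interpretation = interp, tolerance = selfSimTol)
}

#' Permutation comparison of global-integration slopes between two groups
#'
#' The statistic is the absolute slope difference; the null is built by
#' permuting specimens between the two groups (sizes preserved) and
#' recomputing both slopes. Ties count as at least as extreme, so identical
#' samples give p = 1.
#'
#' @param a,b \linkS4class{AlignedShapes} or \code{k x 2 x n} arrays over the
#'   same landmark template.
#' @param spectrum the common \linkS4class{BendingSpectrum} (both groups
#'   share the reference).
#' @inheritParams globalIntegrationSlope
#' @param nperm number of permutations.
#' @param seed integer seed.
#' @return list with \code{slopeA}, \code{slopeB}, \code{diff}, \code{p}.
#' @export
compareGlobalIntegration <- function(a, b, spectrum, nperm = 999,
                                     seed = NULL, perCoordinate = FALSE) {
  aa <- if (is(a, "AlignedShapes")) a@coords else a
  bb <- if (is(b, "AlignedShapes")) b@coords else b
  na <- dim(aa)[3]; nb <- dim(bb)[3]
  sa <- .giSlope(aa, spectrum, perCoordinate)[2]
  sb <- .giSlope(bb, spectrum, perCoordinate)[2]
  obs <- abs(sa - sb)
  pool <- array(c(aa, bb), dim = c(dim(aa)[1], 2L, na + nb))
  perms <- .permIndices(na + nb, nperm, seed)
  cnt <- 0
  for (i in seq_len(nperm)) {
    ia <- perms[i, seq_len(na)]
    ib <- perms[i, na + seq_len(nb)]
    d <- abs(.giSlope(pool[, , ia, drop = FALSE], spectrum,
                      perCoordinate)[2] -
             .giSlope(pool[, , ib, drop = FALSE], spectrum,
                      perCoordinate)[2])
    if (d >= obs - 1e-12) cnt <- cnt + 1
  }
  list(slopeA = unname(sa), slopeB = unname(sb), diff = unname(obs),
       p = (cnt + 1) / (nperm + 1))
}
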