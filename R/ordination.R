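#' Between-group principal component analysis
#'
#' Eigen-decomposition of the covariance of the (equally weighted) group mean
#' vectors; all specimens are projected onto those axes after centering on
#' the grand mean of the group means. Because only group means are
#' decomposed, the method behaves well when per-group sample sizes are
#' smaller than the number of variables. At most (number of groups - 1) axes
#' carry variance.
#'
#' Per-axis percent variance is reported both relative to the group-mean
#' covariance total (\code{percentVar}, summing to 100 over returned axes)
#' and relative to the total sample variance (\code{percentVarTotal}), since
#' published figures use either convention.
#'
#' @param shapes \code{n x p} matrix of shape variables (e.g. flattened
#'   Procrustes coordinates), or an \linkS4class{AlignedShapes}.
#' @param groups factor or character vector of group labels (a typical
#'   usage groups specimens by species).
#' @param tol relative eigenvalue tolerance below which axes are dropped.
#' @return a \linkS4class{BgPcaResult}; axis signs are standardized (largest
#'   magnitude loading positive) for determinism.
#' @export
bgPCA <- function(shapes, groups, tol = 1e-10) {
  Y <- if (is(shapes, "AlignedShapes")) .toMatrix(shapes@coords) else
    as.matrix(shapes)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("bgPCA needs at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (length(groups) != nrow(Y)) stop("one group label per specimen required")
  M <- t(vapply(levels(groups),
                function(g) colMeans(Y[groups == g, , drop = FALSE]),
                numeric(ncol(Y))))
  center <- colMeans(M)
  Mc <- sweep(M, 2, center)
  e <- eigen(stats::cov(Mc), symmetric = TRUE)
  pos <- which(e$values > tol * max(e$values, 0))
  pos <- pos[pos <= nlevels(groups) - 1L]
  axes <- e$vectors[, pos, drop = FALSE]
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- sweep(Y, 2, center) %*% axes
  gm <- Mc %*% axes
  evals <- e$values[pos]
  totalSample <- sum(apply(Y, 2, stats::var))
  new("BgPcaResult", axes = axes, scores = scores, groupMeanScores = gm,
      percentVar = 100 * evals / sum(evals),
      percentVarTotal = 100 * apply(scores, 2, stats::var) / totalSample,
      center = center)
}
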