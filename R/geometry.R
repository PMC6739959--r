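#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid: the size variable of geometric morphometrics.
#'
#' @param x a \code{k x 2} matrix, or a \linkS4class{LandmarkSet} (one value
#'   per specimen).
#' @return a positive number (or vector).
#' @examples
#' sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
#' centroidSize(sq)  # 2 * sqrt(2)
#' @export
centroidSize <- function(x) {
  if (is(x, "LandmarkSet"))
    return(apply(x@coords, 3, centroidSize))
  .assertFinite(x, "coordinates")
  cs <- sqrt(sum(.center(x)^2))
  if (cs == 0) stop("degenerate configuration: all points coincide")
  cs
}

# Center and scale a k x 2 matrix to unit centroid size.
.preshape <- function(m) {
  m <- .center(m)
  m / sqrt(sum(m^2))
}

# Optimal rotation (optionally with scaling) of unit-CS centred `x` onto
# unit-CS centred `y`. Returns list(aligned, rot, scale, distance).
.opa <- function(x, y, allowReflection = FALSE, scale = FALSE) {
  M <- crossprod(x, y)
  sv <- svd(M)
  s <- c(1, 1)
  if (!allowReflection && det(sv$u %*% t(sv$v)) < 0) s <- c(1, -1)
  R <- sv$u %*% diag(s) %*% t(sv$v)
  beta <- if (scale) sum(sv$d * s) / sum(x^2) else 1
  aligned <- beta * x %*% R
  list(aligned = aligned, rot = R, scale = beta,
       distance = sqrt(sum((aligned - y)^2)))
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Centers and scales both configurations to unit centroid size, then rotates
#' the source onto the target by the orthogonal matrix from the SVD of their
#' cross-product. With \code{allowReflection = FALSE} (the default,
#' appropriate for consistently sided structures) the rotation determinant is
#' forced to +1 by sign-flipping the smallest singular direction.
#'
#' @param source,target \code{k x 2} matrices with equal k.
#' @param allowReflection permit improper rotations.
#' @return list with elements \code{aligned} (the transformed source),
#'   \code{rotation} and \code{distance} (the residual Procrustes distance;
#'   0 iff the shapes are identical up to a similarity transform).
#' @export
alignOptimal <- function(source, target, allowReflection = FALSE) {
  if (!identical(dim(source), dim(target)))
    stop("shape mismatch: source and target must have equal landmark counts")
  xs <- .preshape(source)
  ys <- .preshape(target)
  fit <- .opa(xs, ys, allowReflection = allowReflection, scale = FALSE)
  list(aligned = fit$aligned, rotation = fit$rot, distance = fit$distance)
}

#' Procrustes distance between two configurations
#'
#' @inheritParams alignOptimal
#' @param a,b \code{k x 2} matrices.
#' @return the residual root summed squared coordinate difference after
#'   optimal superimposition.
#' @export
procrustesDistance <- function(a, b, allowReflection = FALSE) {
  alignOptimal(a, b, allowReflection)$distance
}

#' Generalized Procrustes analysis
#'
#' Iteratively removes translation, scale and rotation from a sample of
#' configurations: all shapes are centred and scaled to unit centroid size,
#' aligned to a provisional consensus by full Procrustes fitting (rotation
#' and scaling), and the consensus re-estimated and rescaled to unit centroid
#' size, until the root-mean-squared consensus change falls below \code{tol}
#' or \code{maxIter} is reached. When a slider table is supplied, a
#' semilandmark sliding pass (see [slideSemilandmarks()]) is interleaved
#' after the consensus update, for at most \code{maxSlidePasses} passes.
#' Centroid sizes are recorded from the original configurations.
#'
#' @param x a \linkS4class{LandmarkSet} or \code{k x 2 x n} array, n >= 2.
#' @param sliders optional slider table (\code{before, slider, after},
#'   1-based), see [validateSliderTable()].
#' @param method sliding criterion: \code{"none"}, \code{"BEN"} (minimum
#'   bending energy) or \code{"PRD"} (minimum Procrustes distance).
#' @param tol RMS consensus-change convergence tolerance.
#' @param maxIter iteration cap; non-convergence yields a warning recorded in
#'   the result, not an error.
#' @param maxSlidePasses maximum number of sliding passes.
#' @param allowReflection permit improper rotations.
#' @return an \linkS4class{AlignedShapes}.
#' @export
gpa <- function(x, sliders = NULL, method = c("none", "BEN", "PRD"),
                tol = 1e-10, maxIter = 100, maxSlidePasses = 3,
                allowReflection = FALSE) {
  method <- match.arg(method)
  a <- if (is(x, "LandmarkSet")) x@coords else x
  d <- dim(a)
  if (is.null(d) || length(d) != 3L) stop("expected a k x 2 x n array")
  k <- d[1]; n <- d[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  if (method != "none" && is.null(sliders))
    stop("sliding method ", method, " requires a slider table")
  if (!is.null(sliders)) sliders <- validateSliderTable(sliders, k = k)
  cs <- apply(a, 3, centroidSize)
  X <- array(apply(a, 3, .preshape), dim = d, dimnames = dimnames(a))

  consensus <- .preshape(apply(X, c(1, 2), mean))
  slidePass <- 0L
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    obj <- 0
    for (i in seq_len(n)) {
      fit <- .opa(.preshape(X[, , i]), consensus,
                  allowReflection = allowReflection, scale = TRUE)
      X[, , i] <- fit$aligned
      obj <- obj + fit$distance^2
    }
    history <- c(history, obj)
    newCons <- .preshape(apply(X, c(1, 2), mean))
    delta <- sqrt(mean((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol) {
      if (method != "none" && slidePass < maxSlidePasses) {
        X <- slideSemilandmarks(X, consensus, sliders, method,
                                reAlign = FALSE)
        slidePass <- slidePass + 1L
      } else {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) warning("GPA did not converge in ", maxIter, " iterations")
  new("AlignedShapes", coords = X, centroidSizes = cs, consensus = consensus,
      slidingMethod = method, converged = converged, iterations = iter,
      history = history)
}

#' Slide semilandmarks along their tangent directions
#'
#' Each semilandmark moves only along the unit chord from its \code{before}
#' to its \code{after} neighbour at the current shape. Displacements are
#' chosen per specimen to minimize either the thin-plate-spline bending
#' energy of the consensus-to-specimen map (\code{"BEN"}, a generalized
#' least-squares solution restricted to the tangent directions) or the summed
#' squared distance to the consensus (\code{"PRD"}, orthogonal projection of
#' the consensus residual onto the tangent).
#'
#' @param shapes \code{k x 2 x n} array of shapes superimposed on
#'   \code{consensus}.
#' @param consensus \code{k x 2} reference.
#' @param sliders slider table (\code{before, slider, after}, 1-based).
#' @param method \code{"BEN"} or \code{"PRD"}.
#' @param reAlign re-superimpose each slid shape onto the consensus
#'   afterwards (full Procrustes fit).
#' @return the adjusted \code{k x 2 x n} array.
#' @export
slideSemilandmarks <- function(shapes, consensus, sliders,
                               method = c("BEN", "PRD"), reAlign = TRUE) {
  method <- match.arg(method)
  k <- dim(shapes)[1]
  n <- dim(shapes)[3]
  sliders <- validateSliderTable(sliders, k = k)
  Be <- if (method == "BEN") .bendingEnergyMatrix(consensus) else NULL
  out <- shapes
  for (i in seq_len(n)) {
    Y <- shapes[, , i]
    tx <- Y[sliders$after, 1] - Y[sliders$before, 1]
    ty <- Y[sliders$after, 2] - Y[sliders$before, 2]
    len <- sqrt(tx^2 + ty^2)
    keep <- len > 1e-12
    if (!all(keep))
      warning("zero-length tangent at slider(s) ",
              paste(sliders$slider[!keep], collapse = ", "), "; skipped")
    if (!any(keep)) next
    sl <- sliders$slider[keep]
    tx <- tx[keep] / len[keep]
    ty <- ty[keep] / len[keep]
    if (method == "PRD") {
      delta <- tx * (consensus[sl, 1] - Y[sl, 1]) +
               ty * (consensus[sl, 2] - Y[sl, 2])
    } else {
      m <- length(sl)
      # E2 %*% T built column-wise: column j touches source row sl[j] in each
      # coordinate block.
      ET <- rbind(Be[, sl, drop = FALSE] %*% diag(tx, m),
                  Be[, sl, drop = FALSE] %*% diag(ty, m))
      A <- crossprod(rbind(diag(tx, m), diag(ty, m)),
                     rbind(ET[sl, , drop = FALSE],
                           ET[k + sl, , drop = FALSE]))
      b <- as.numeric(crossprod(ET, c(Y[, 1], Y[, 2])))
      delta <- tryCatch(-solve(A, b),
                        error = function(e)
                          -as.numeric(MASS::ginv(A) %*% b))
    }
    Y[sl, 1] <- Y[sl, 1] + delta * tx
    Y[sl, 2] <- Y[sl, 2] + delta * ty
    if (reAlign) Y <- .opa(.preshape(Y), consensus, scale = TRUE)$aligned
    out[, , i] <- Y
  }
  out
}

#' Digitization measurement error
#'
#' Quantifies digitization error as a percentage of total shape variation:
#' after a joint generalized Procrustes analysis of all replicate
#' digitizations, the mean within-triplet pairwise Procrustes distance
#' (averaged over specimens) is divided by the mean pairwise distance among
#' the specimens' consensus forms, both measured in the same aligned space.
#'
#' @param replicates a list of exactly 3 \linkS4class{LandmarkSet}s holding
#'   the same specimens (matched by specimen id).
#' @return the error percentage (0 for bit-identical replicas).
#' @export
measurementError <- function(replicates) {
  if (length(replicates) != 3L)
    stop("unsupported design: exactly 3 replicate datasets are required")
  ids <- specimenIDs(replicates[[1]])
  for (r in replicates[2:3]) {
    if (!setequal(specimenIDs(r), ids))
      stop("replicate datasets do not hold the same specimen ids")
  }
  k <- nLandmarks(replicates[[1]])
  n <- length(ids)
  all <- array(0, dim = c(k, 2L, 3L * n))
  for (r in 1:3) {
    cc <- coords(replicates[[r]])
    all[, , (r - 1L) * n + seq_len(n)] <- cc[, , match(ids, specimenIDs(replicates[[r]]))]
  }
  dimnames(all) <- list(NULL, c("x", "y"), paste0(rep(ids, 3), "_r",
                                                  rep(1:3, each = n)))
  al <- gpa(all)@coords
  within <- numeric(n)
  consForms <- array(0, dim = c(k, 2L, n))
  for (i in seq_len(n)) {
    tri <- al[, , c(i, n + i, 2L * n + i)]
    pw <- c(sqrt(sum((tri[, , 1] - tri[, , 2])^2)),
            sqrt(sum((tri[, , 1] - tri[, , 3])^2)),
            sqrt(sum((tri[, , 2] - tri[, , 3])^2)))
    within[i] <- mean(pw)
    consForms[, , i] <- apply(tri, c(1, 2), mean)
  }
  among <- numeric(0)
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n))
      among <- c(among, sqrt(sum((consForms[, , i] - consForms[, , j])^2)))
  100 * mean(within) / mean(among)
}
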