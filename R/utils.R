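# Internal helpers shared across modules.

# Flatten k x 2 x n array to n x 2k matrix (x1..xk then y1..yk).
.toMatrix <- function(a) {
  d <- dim(a)
  m <- t(apply(a, 3, function(s) c(s[, 1], s[, 2])))
  if (d[3] == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- dimnames(a)[[3]]
  m
}

# Inverse of .toMatrix.
.toArray <- function(m, k) {
  n <- nrow(m)
  a <- array(0, dim = c(k, 2L, n), dimnames = list(NULL, c("x", "y"),
                                                   rownames(m)))
  for (i in seq_len(n)) a[, , i] <- cbind(m[i, seq_len(k)],
                                          m[i, k + seq_len(k)])
  a
}

.center <- function(m) sweep(m, 2, colMeans(m))

# Draw nperm row permutations of 1..n reproducibly without disturbing the
# caller's RNG state.
.permIndices <- function(n, nperm, seed) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  matrix(replicate(nperm, sample.int(n)), nrow = nperm, byrow = TRUE)
}

# Permutation p-value including the observed statistic; ties count as >=.
.permP <- function(obs, perm) (sum(perm >= obs - 1e-12) + 1) / (length(perm) + 1)

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
}

#' Build a LandmarkSet from a coordinate array or list of matrices
#'
#' @param coords a \code{k x 2 x n} array, a single \code{k x 2} matrix, or a
#'   list of \code{k x 2} matrices.
#' @param ids specimen identifiers; defaults to existing dimnames or
#'   \code{spec1..specn}.
#' @param scales optional per-specimen image scale factors.
#' @param metadata optional list of free-form metadata.
#' @return a \linkS4class{LandmarkSet}.
#' @examples
#' tri <- matrix(c(0, 1, 0, 0, 0, 1), ncol = 2)
#' landmarkSet(tri, ids = "t1")
#' @export
landmarkSet <- function(coords, ids = NULL, scales = numeric(0),
                        metadata = list()) {
  if (is.list(coords) && !is.array(coords)) {
    k <- nrow(coords[[1]])
    a <- array(0, dim = c(k, 2L, length(coords)))
    for (i in seq_along(coords)) a[, , i] <- as.matrix(coords[[i]])
    if (is.null(ids)) ids <- names(coords)
    coords <- a
  } else if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), 2L, 1L))
  }
  n <- dim(coords)[3]
  if (is.null(ids)) ids <- dimnames(coords)[[3]]
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  dimnames(coords) <- list(NULL, c("x", "y"), ids)
  new("LandmarkSet", coords = coords, scales = scales, metadata = metadata)
}
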