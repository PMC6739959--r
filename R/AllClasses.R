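#' @import methods
NULL

#' Set of 2D landmark configurations
#'
#' Container for one or more digitized specimens sharing a landmark template:
#' a \code{k x 2 x n} array of coordinates whose third dimension is named by
#' specimen id. Point order is the homology order and is never permuted by
#' I/O or analysis code.
#'
#' @slot coords numeric array, \code{k x 2 x n}, finite coordinates.
#' @slot scales optional numeric vector of per-specimen image scale factors
#'   (length 0 or n, positive). Stored, not applied, unless requested at read
#'   time.
#' @slot metadata free-form list (e.g. IMAGE= lines from a TPS file).
#' @export
setClass("LandmarkSet",
  slots = c(coords = "array", scales = "numeric", metadata = "list"),
  prototype = prototype(scales = numeric(0), metadata = list()))

setValidity("LandmarkSet", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L) return("coords must be a k x 2 x n array")
  if (d[2] != 2L) return("coords must have 2 coordinate columns (2D only)")
  if (d[1] < 3L) return("at least 3 landmarks are required")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  ids <- dimnames(object@coords)[[3]]
  if (d[3] > 0L && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    return("specimen ids (dimnames[[3]]) must be unique and non-empty")
  if (length(object@scales) && length(object@scales) != d[3])
    return("scales must be empty or one per specimen")
  if (length(object@scales) && any(object@scales <= 0))
    return("scale factors must be positive")
  TRUE
})

#' Procrustes-superimposed sample
#'
#' Result of generalized Procrustes analysis: aligned shape coordinates, the
#' centroid sizes of the original configurations, the unit-centroid-size
#' consensus, and the semilandmark sliding method used.
#'
#' @slot coords aligned coordinates, \code{k x 2 x n}; each shape centred at
#'   the origin.
#' @slot centroidSizes centroid sizes of the original (unaligned)
#'   configurations.
#' @slot consensus \code{k x 2} mean shape, centroid size 1.
#' @slot slidingMethod one of \code{"none"}, \code{"BEN"}, \code{"PRD"}.
#' @slot converged logical; \code{FALSE} records non-convergence (a warning,
#'   not an error).
#' @slot iterations number of GPA iterations performed.
#' @slot history summed squared Procrustes distance to the consensus at each
#'   iteration (monotone non-increasing between sliding passes).
#' @export
setClass("AlignedShapes",
  slots = c(coords = "array", centroidSizes = "numeric", consensus = "matrix",
            slidingMethod = "character", converged = "logical",
            iterations = "numeric", history = "numeric"))

setValidity("AlignedShapes", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 2L) return("coords must be k x 2 x n")
  if (d[3] < 2L) return("an aligned sample needs at least 2 specimens")
  if (length(object@centroidSizes) != d[3])
    return("one centroid size per specimen required")
  if (any(object@centroidSizes <= 0)) return("centroid sizes must be positive")
  cent <- apply(object@coords, 3, function(m) max(abs(colMeans(m))))
  if (max(cent) > 1e-8) return("aligned shapes must be centred at the origin")
  cs <- sqrt(sum(scale(object@consensus, scale = FALSE)^2))
  if (abs(cs - 1) > 1e-8) return("consensus must have unit centroid size")
  if (!object@slidingMethod %in% c("none", "BEN", "PRD"))
    return("slidingMethod must be none, BEN or PRD")
  TRUE
})

#' Thin-plate-spline interpolation model
#'
#' Coefficients of the 2D thin-plate-spline map taking \code{source} exactly
#' onto \code{target}, with kernel U(r) = r^2 log(r^2). The affine part is a
#' 3 x 2 matrix (rows: intercept, x, y) and the non-affine weights are k x 2,
#' satisfying the usual side conditions (columns sum to zero and are
#' orthogonal to the source coordinates).
#'
#' @slot source,target \code{k x 2} matrices.
#' @slot affine \code{3 x 2} affine coefficients.
#' @slot weights \code{k x 2} non-affine kernel weights.
#' @export
setClass("TpsModel",
  slots = c(source = "matrix", target = "matrix", affine = "matrix",
            weights = "matrix"))

setValidity("TpsModel", function(object) {
  k <- nrow(object@source)
  if (!identical(dim(object@source), dim(object@target)))
    return("source and target must have equal dimensions")
  if (!identical(dim(object@affine), c(3L, 2L))) return("affine must be 3 x 2")
  if (!identical(dim(object@weights), c(k, 2L))) return("weights must be k x 2")
  TRUE
})

#' Bending-energy spectrum of a reference configuration
#'
#' Eigendecomposition of the k x k bending-energy matrix computed at a
#' reference shape (typically the GPA consensus): the k - 3 strictly positive
#' eigenvalues in ascending order and their orthonormal eigenvectors, the
#' partial-warp directions.
#'
#' @slot values positive eigenvalues, ascending, length k - 3.
#' @slot vectors \code{k x (k-3)} orthonormal eigenvectors.
#' @slot reference the \code{k x 2} configuration the spectrum was computed at.
#' @export
setClass("BendingSpectrum",
  slots = c(values = "numeric", vectors = "matrix", reference = "matrix"))

setValidity("BendingSpectrum", function(object) {
  k <- nrow(object@reference)
  if (length(object@values) != k - 3L)
    return("a 2D reference has exactly k - 3 positive bending eigenvalues")
  if (any(object@values <= 0)) return("bending eigenvalues must be positive")
  if (is.unsorted(object@values)) return("eigenvalues must be ascending")
  if (!identical(dim(object@vectors), c(k, k - 3L)))
    return("vectors must be k x (k-3)")
  TRUE
})

#' Two-block partial least squares result
#'
#' Singular-value decomposition of the cross-covariance between two blocks of
#' variables measured on the same specimens, with permutation inference on
#' the first axis pair and a standardized integration effect size.
#'
#' @slot singularValues singular values, descending.
#' @slot xScores,yScores specimen scores on the paired singular vectors.
#' @slot xLoadings,yLoadings singular vectors (columns).
#' @slot cors Pearson correlation of paired scores per axis; axis 1 is
#'   oriented so its correlation is non-negative.
#' @slot pValue permutation p-value for the axis-1 correlation (r-PLS).
#' @slot permDist permuted r-PLS values.
#' @slot effectSize standardized effect size z (Fisher-stabilized).
#' @slot effectSizeSE its standard error, estimated from the permutation
#'   distribution.
#' @slot nperm number of permutations.
#' @export
setClass("PlsResult",
  slots = c(singularValues = "numeric", xScores = "matrix", yScores = "matrix",
            xLoadings = "matrix", yLoadings = "matrix", cors = "numeric",
            pValue = "numeric", permDist = "numeric", effectSize = "numeric",
            effectSizeSE = "numeric", nperm = "numeric"))

#' Permutation ANOVA table
#'
#' Sequential (type-I) multivariate ANOVA fitted by residual randomization
#' (RRPP): per model term the df, sums of squares, mean squares, F, an effect
#' size Z (standard deviate of log F against its permutation distribution)
#' and the permutation p-value.
#'
#' @slot table data.frame with one row per term plus residuals/total rows.
#' @slot nperm number of permutations.
#' @slot scheme \code{"RRPP"} (reduced-model residual permutation) or
#'   \code{"raw"} (raw-value permutation).
#' @export
setClass("AnovaResult",
  slots = c(table = "data.frame", nperm = "numeric", scheme = "character"))

#' Group disparity (Procrustes variance) result
#'
#' @slot variances named per-group Procrustes variances (mean squared
#'   deviation from the group mean).
#' @slot pairwiseDiff matrix of absolute pairwise variance differences.
#' @slot pairwiseP matrix of permutation p-values.
#' @slot nperm number of permutations.
#' @export
setClass("DisparityResult",
  slots = c(variances = "numeric", pairwiseDiff = "matrix",
            pairwiseP = "matrix", nperm = "numeric"))

#' Global (intrinsic) integration regression
#'
#' Ordinary least-squares regression of log partial-warp variance on log
#' bending energy. A slope below -1 indicates integration, a slope above -1
#' dis-integration, and a slope of exactly -1 self-similarity.
#'
#' @slot slope,intercept regression coefficients.
#' @slot points data.frame of (logLambda, logVariance) pairs used.
#' @slot interpretation one of \code{"integrated"}, \code{"self-similar"},
#'   \code{"dis-integrated"}.
#' @slot tolerance half-width of the self-similarity band around -1.
#' @export
setClass("GlobalIntegrationResult",
  slots = c(slope = "numeric", intercept = "numeric", points = "data.frame",
            interpretation = "character", tolerance = "numeric"))

setValidity("GlobalIntegrationResult", function(object) {
  ok <- if (object@slope < -1 - object@tolerance) "integrated"
        else if (object@slope > -1 + object@tolerance) "dis-integrated"
        else "self-similar"
  if (!identical(object@interpretation, ok))
    return("interpretation inconsistent with slope and tolerance")
  TRUE
})

#' Multivariate phylogenetic signal (Kmult)
#'
#' @slot statistic the Kmult statistic (>= 0); 1 is the Brownian-motion
#'   expectation.
#' @slot pValue permutation p-value (NA when nperm = 0).
#' @slot nperm number of permutations.
#' @export
setClass("KmultResult",
  slots = c(statistic = "numeric", pValue = "numeric", nperm = "numeric"))

#' Between-group PCA result
#'
#' Principal components of the (equally weighted) group mean configurations,
#' with all specimens projected onto those axes.
#'
#' @slot axes orthonormal loading vectors (variables x axes).
#' @slot scores specimen scores.
#' @slot groupMeanScores projected group means.
#' @slot percentVar per-axis percent of group-mean variance (sums to 100
#'   over returned axes).
#' @slot percentVarTotal per-axis percent of total sample variance (the
#'   alternative convention, reported alongside).
#' @slot center grand mean of the group means used for centering.
#' @export
setClass("BgPcaResult",
  slots = c(axes = "matrix", scores = "matrix", groupMeanScores = "matrix",
            percentVar = "numeric", percentVarTotal = "numeric",
            center = "numeric"))
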