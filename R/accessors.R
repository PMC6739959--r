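#' @describeIn LandmarkSet coordinate array
#' @param object a \code{LandmarkSet}.
#' @export
setMethod("coords", "LandmarkSet", function(object) object@coords)

#' @describeIn AlignedShapes aligned coordinate array
#' @param object an \code{AlignedShapes}.
#' @export
setMethod("coords", "AlignedShapes", function(object) object@coords)

#' @export
#' @describeIn LandmarkSet number of landmarks
setMethod("nLandmarks", "LandmarkSet", function(object) dim(object@coords)[1])

#' @export
#' @describeIn AlignedShapes number of landmarks
setMethod("nLandmarks", "AlignedShapes", function(object) dim(object@coords)[1])

#' @export
#' @describeIn LandmarkSet number of specimens
setMethod("nSpecimens", "LandmarkSet", function(object) dim(object@coords)[3])

#' @export
#' @describeIn AlignedShapes number of specimens
setMethod("nSpecimens", "AlignedShapes", function(object) dim(object@coords)[3])

#' @export
#' @describeIn LandmarkSet specimen ids
setMethod("specimenIDs", "LandmarkSet",
          function(object) dimnames(object@coords)[[3]])

#' @export
#' @describeIn AlignedShapes specimen ids
setMethod("specimenIDs", "AlignedShapes",
          function(object) dimnames(object@coords)[[3]])

#' @export
#' @describeIn AlignedShapes centroid sizes of the original configurations
setMethod("centroidSizes", "AlignedShapes", function(object)
  object@centroidSizes)

#' @export
#' @describeIn AlignedShapes consensus shape (k x 2, unit centroid size)
setMethod("consensusShape", "AlignedShapes", function(object) object@consensus)

#' @export
#' @describeIn AnovaResult the per-term table
setMethod("anovaTable", "AnovaResult", function(object) object@table)

#' @export
#' @describeIn PlsResult effect size and its standard error
setMethod("effectSize", "PlsResult", function(object, ...)
  c(z = object@effectSize, se = object@effectSizeSE))

setMethod("show", "LandmarkSet", function(object) {
  d <- dim(object@coords)
  cat("LandmarkSet:", d[3], "specimen(s),", d[1], "landmarks (2D)\n")
  if (length(object@scales)) cat("  image scale factors stored\n")
})

setMethod("show", "AlignedShapes", function(object) {
  d <- dim(object@coords)
  cat("AlignedShapes:", d[3], "specimen(s),", d[1], "landmarks\n")
  cat("  sliding:", object@slidingMethod,
      "| iterations:", object@iterations,
      "| converged:", object@converged, "\n")
  cat("  centroid size range: [",
      format(min(object@centroidSizes), digits = 4), ", ",
      format(max(object@centroidSizes), digits = 4), "]\n", sep = "")
})

setMethod("show", "TpsModel", function(object) {
  cat("TpsModel:", nrow(object@source), "landmarks, bending energy",
      format(bendingEnergy(object), digits = 6), "\n")
})

setMethod("show", "BendingSpectrum", function(object) {
  cat("BendingSpectrum:", length(object@values),
      "positive eigenvalues, range [",
      format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = " ")
})

setMethod("show", "PlsResult", function(object) {
  cat("Two-block PLS: r-PLS (axis 1) =", format(object@cors[1], digits = 4))
  if (is.finite(object@pValue)) cat(", p =", format(object@pValue, digits = 4))
  cat("\n")
  if (is.finite(object@effectSize))
    cat("  effect size z =", format(object@effectSize, digits = 4),
        "(se", format(object@effectSizeSE, digits = 3), ")\n")
})

setMethod("show", "AnovaResult", function(object) {
  cat("Permutation ANOVA (", object@scheme, ", ", object@nperm,
      " permutations)\n", sep = "")
  print(object@table, digits = 4)
})

setMethod("show", "DisparityResult", function(object) {
  cat("Procrustes variance by group:\n")
  print(object@variances, digits = 4)
  cat("Pairwise permutation p-values:\n")
  print(object@pairwiseP, digits = 3)
})

setMethod("show", "GlobalIntegrationResult", function(object) {
  cat("Global integration: slope =", format(object@slope, digits = 4),
      "->", object@interpretation, "\n")
})

setMethod("show", "KmultResult", function(object) {
  cat("Kmult =", format(object@statistic, digits = 4))
  if (is.finite(object@pValue)) cat(", p =", format(object@pValue, digits = 4))
  cat("\n")
})

setMethod("show", "BgPcaResult", function(object) {
  cat("Between-group PCA:", ncol(object@axes), "axes\n")
  cat("  % of group-mean variance:",
      paste(format(object@percentVar, digits = 3), collapse = ", "), "\n")
})
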