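#' Extract landmark coordinates
#'
#' @param object a \linkS4class{LandmarkSet} or \linkS4class{AlignedShapes}.
#' @return the \code{k x 2 x n} coordinate array.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' Number of landmarks per configuration
#' @param object a coordinate container.
#' @export
setGeneric("nLandmarks", function(object) standardGeneric("nLandmarks"))

#' Number of specimens
#' @param object a coordinate container.
#' @export
setGeneric("nSpecimens", function(object) standardGeneric("nSpecimens"))

#' Specimen identifiers
#' @param object a coordinate container.
#' @export
setGeneric("specimenIDs", function(object) standardGeneric("specimenIDs"))

#' Centroid sizes of the original configurations
#' @param object an \linkS4class{AlignedShapes}.
#' @export
setGeneric("centroidSizes", function(object) standardGeneric("centroidSizes"))

#' Consensus (mean) shape of an aligned sample
#' @param object an \linkS4class{AlignedShapes}.
#' @export
setGeneric("consensusShape", function(object) standardGeneric("consensusShape"))

#' ANOVA table of a permutation linear model
#' @param object an \linkS4class{AnovaResult}.
#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))

#' Integration effect size (standardized r-PLS)
#' @param object a \linkS4class{PlsResult}.
#' @param ... further arguments.
#' @export
setGeneric("effectSize", function(object, ...) standardGeneric("effectSize"))
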