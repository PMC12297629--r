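#' @rdname PatchGrid-class
#' @param object,x a \code{PatchGrid}, \code{HotspotMap} or other package object
#' @export
setGeneric("slideId", function(object) standardGeneric("slideId"))

#' @rdname PatchGrid-class
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname PatchGrid-class
#' @export
setGeneric("gridDims", function(object) standardGeneric("gridDims"))

#' @rdname PatchGrid-class
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))

#' @rdname TILScore-class
#' @param object a \code{TILScore}
#' @export
setGeneric("scoreValue", function(object) standardGeneric("scoreValue"))

#' @rdname HotspotMap-class
#' @param object a \code{HotspotMap}
#' @export
setGeneric("zScores", function(object) standardGeneric("zScores"))

#' Fraction of tissue patches whose Gi* z-score reaches the hot threshold
#'
#' @param object a [HotspotMap-class]
#' @return numeric(1) in [0, 1]
#' @export
setGeneric("hotFraction", function(object) standardGeneric("hotFraction"))

#' @rdname HotspotMap-class
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))

#' @rdname ConsensusVote-class
#' @param object a \code{ConsensusVote} or \code{SpatialFeatureSet}
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))

#' @rdname SpatialFeatureSet-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname SpatialFeatureSet-class
#' @export
setGeneric("stilcLabels", function(object) standardGeneric("stilcLabels"))

# -- accessors -----------------------------------------------------------

#' @rdname PatchGrid-class
#' @export
setMethod("slideId", "PatchGrid", function(object) object@slideId)

#' @rdname HotspotMap-class
#' @export
setMethod("slideId", "HotspotMap", function(object) object@slideId)

#' @rdname PatchGrid-class
#' @export
setMethod("patientId", "PatchGrid", function(object) object@patientId)

#' @rdname PatchGrid-class
#' @export
setMethod("gridDims", "PatchGrid",
          function(object) c(nRows = object@nRows, nCols = object@nCols))

#' @rdname HotspotMap-class
#' @export
setMethod("gridDims", "HotspotMap",
          function(object) c(nRows = object@nRows, nCols = object@nCols))

#' @rdname PatchGrid-class
#' @export
setMethod("patches", "PatchGrid", function(object) object@patches)

#' @rdname TILScore-class
#' @export
setMethod("scoreValue", "TILScore", function(object) object@value)

#' @rdname HotspotMap-class
#' @export
setMethod("zScores", "HotspotMap", function(object) object@z)

#' @rdname hotFraction
#' @export
setMethod("hotFraction", "HotspotMap",
          function(object) mean(object@z >= object@hotThreshold))

#' @rdname HotspotMap-class
#' @export
setMethod("isDegenerate", "HotspotMap", function(object) object@degenerate)

#' @rdname ConsensusVote-class
#' @export
setMethod("selectedK", "ConsensusVote", function(object) object@selectedK)

#' @rdname SpatialFeatureSet-class
#' @export
setMethod("selectedK", "SpatialFeatureSet", function(object) {
  if (is.null(object@vote)) stop("no consensus vote stored yet")
  object@vote@selectedK
})

#' @rdname SpatialFeatureSet-class
#' @export
setMethod("clusterLabels", "SpatialFeatureSet", function(object) {
  structure(object@clusterLabels, names = object@slideIds)
})

#' @rdname SpatialFeatureSet-class
#' @export
setMethod("stilcLabels", "SpatialFeatureSet", function(object) {
  structure(object@stilcLabels, names = object@slideIds)
})

# -- show methods --------------------------------------------------------

setMethod("show", "PatchGrid", function(object) {
  tab <- table(object@patches$label)
  cat("PatchGrid", object@slideId, "(patient", paste0(object@patientId, ")"),
      "\n  lattice:", object@nRows, "x", object@nCols,
      " tissue patches:", nrow(object@patches), "\n  labels:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "TILScore", function(object) {
  cat(sprintf("TILScore %.4f (%d TIL-positive / %d scoreable patches)\n",
              object@value, object@nPos, object@nTissue))
})

setMethod("show", "SpatialWeights", function(object) {
  cat("SpatialWeights:", object@n, "patches,", object@scheme, "contiguity,",
      if (object@includeSelf) "self-inclusive (Gi*)\n" else "no self (Gi)\n")
})

setMethod("show", "HotspotMap", function(object) {
  cat(sprintf(
    "HotspotMap %s: %d tissue patches on %d x %d, hot fraction %.3f (z >= %.2f)%s\n",
    object@slideId, length(object@z), object@nRows, object@nCols,
    hotFraction(object), object@hotThreshold,
    if (object@degenerate) " [degenerate field]" else ""))
})

setMethod("show", "ConsensusVote", function(object) {
  cat("ConsensusVote over k in {", paste(object@candidateKs, collapse = ", "),
      "}\n  winners: silhouette=", object@winners[["silhouette"]],
      " daviesBouldin=", object@winners[["daviesBouldin"]],
      " calinskiHarabasz=", object@winners[["calinskiHarabasz"]],
      "\n  selected k =", object@selectedK, "\n")
})

setMethod("show", "SpatialFeatureSet", function(object) {
  cat("SpatialFeatureSet:", length(object@slideIds), "slides,",
      ncol(object@rawFeatures), "raw features,",
      ncol(object@pcaScores), "principal components\n")
  if (length(object@stilcLabels))
    cat("  sTILC:", paste(names(table(object@stilcLabels)),
                          table(object@stilcLabels), sep = "=", collapse = " "), "\n")
})

setMethod("show", "ModelComparisonReport", function(object) {
  cat("ModelComparisonReport across", length(object@cohorts), "cohorts\n")
  for (nm in names(object@cohorts)) {
    co <- object@cohorts[[nm]]
    cat(sprintf(
      "  %s: AUC M1=%.3f M2=%.3f | DeLong z=%.3f p=%.3g | Brier M1=%.3f M2=%.3f\n",
      nm, co$aucM1, co$aucM2, co$delongZ, co$delongP, co$brierM1, co$brierM2))
  }
})
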