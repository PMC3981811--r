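#' Accessors for tubemorph classes
#'
#' Small accessor generics: \code{maskMatrix} returns the logical pixel mask
#' of an [EdgeMask-class] or [SkeletonMask-class]; \code{provenance} the
#' ordered processing steps of an [EdgeMask-class]; \code{intensity} the
#' pixel matrix of a [GrayImage-class]; \code{totalLength},
#' \code{totalArea}, \code{nBranchPoints} and \code{avgThickness} the fields
#' of a [TubeMetrics-class] or [GroundTruth-class]; \code{metrics} the
#' [TubeMetrics-class] of an [AnalysisRecord-class].
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setGeneric("totalArea", function(object) standardGeneric("totalArea"))
#' @rdname accessors
#' @export
setGeneric("nBranchPoints", function(object) standardGeneric("nBranchPoints"))
#' @rdname accessors
#' @export
setGeneric("avgThickness", function(object) standardGeneric("avgThickness"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname accessors
setMethod("maskMatrix", "EdgeMask", function(object) object@mask)
#' @rdname accessors
setMethod("maskMatrix", "SkeletonMask", function(object) object@mask)
#' @rdname accessors
setMethod("provenance", "EdgeMask", function(object) object@provenance)
#' @rdname accessors
setMethod("intensity", "GrayImage", function(object) object@intensity)
#' @rdname accessors
setMethod("totalLength", "TubeMetrics", function(object) object@totalLength)
#' @rdname accessors
setMethod("totalLength", "GroundTruth", function(object) object@totalLength)
#' @rdname accessors
setMethod("totalArea", "TubeMetrics", function(object) object@totalArea)
#' @rdname accessors
setMethod("totalArea", "GroundTruth", function(object) object@totalArea)
#' @rdname accessors
setMethod("nBranchPoints", "TubeMetrics", function(object) object@nBranchPoints)
#' @rdname accessors
setMethod("nBranchPoints", "GroundTruth", function(object) object@nJunctions)
#' @rdname accessors
setMethod("avgThickness", "TubeMetrics", function(object) object@avgThickness)
#' @rdname accessors
setMethod("metrics", "AnalysisRecord", function(object) object@metrics)

setMethod("show", "ParameterProfile", function(object) {
  cat("ParameterProfile (microns/px and pixels)\n")
  cat(sprintf("  scale: %g  cannyConnect: %g  dilate: %g  fill: %g\n",
              object@scale, object@cannyConnect, object@dilate, object@fill))
  cat(sprintf("  clean: %g  clip: %s  overlap: %g  radius: %g\n",
              object@clean, format(object@clip), object@overlap, object@radius))
})

setMethod("show", "EdgeMask", function(object) {
  cat(sprintf("EdgeMask %d x %d, %d foreground px; steps: %s\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              paste(object@provenance, collapse = " -> ")))
})

setMethod("show", "SkeletonMask", function(object) {
  cat(sprintf("SkeletonMask %d x %d, %d backbone px\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask)))
})

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %d x %d, luminance range [%g, %g]\n",
              nrow(object@intensity), ncol(object@intensity),
              object@luminanceRange[1], object@luminanceRange[2]))
})

setMethod("show", "TubeMetrics", function(object) {
  cat("TubeMetrics", if (nzchar(object@sourceFile)) paste0("[", object@sourceFile, "]") else "", "\n")
  cat(sprintf("  total length: %.2f um\n  total area:   %.2f um^2\n", object@totalLength, object@totalArea))
  cat(sprintf("  branch points: %d\n  avg thickness: %s um\n",
              as.integer(object@nBranchPoints),
              ifelse(is.na(object@avgThickness), "NA", sprintf("%.2f", object@avgThickness))))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: length %.2f um, junctions %d, area %.2f um^2\n",
              object@totalLength, as.integer(object@nJunctions), object@totalArea))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d segment(s), width %g px, %d x %d image, noise %g\n",
              nrow(object@segments), object@strokeWidth,
              object@imageSize[1], object@imageSize[2], object@noise))
})

setMethod("show", "AnalysisRecord", function(object) {
  cat("AnalysisRecord:", object@sourceFile, "\n")
  if (nzchar(object@error)) cat("  ERROR:", object@error, "\n") else show(object@metrics)
  if (length(object@outputsWritten))
    cat("  outputs:", paste(basename(object@outputsWritten), collapse = ", "), "\n")
})
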