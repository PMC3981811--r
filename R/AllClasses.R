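#' @import methods
NULL

#' Parameter profile for a tube formation assay analysis
#'
#' Holds the eight user-adjustable parameters that control an analysis, so a
#' profile tuned interactively on one representative image can be reused,
#' unchanged, across a whole batch. All parameters except \code{scale} are in
#' pixels (or pixel counts for the area thresholds).
#'
#' @slot scale microns per pixel (> 0); converts pixel measurements to
#'   physical units. Typical 0.5--5.
#' @slot cannyConnect radius (px) within which detected edge points are
#'   connected into one mask (morphological closing). Typical 2--12.
#' @slot dilate radius (px) of a second closing pass that merges nearby
#'   objects and suppresses noise. Typical 2--7.
#' @slot fill enclosed background regions strictly smaller than this many
#'   pixels are filled in (false-negative holes inside tubes). Typical
#'   200--5000+.
#' @slot clean foreground objects strictly smaller than this many pixels are
#'   cleared (false-positive specks). Typical 1000--10000+.
#' @slot clip number of pixels trimmed inward from every skeleton endpoint,
#'   stopping early at a branch point; \code{Inf} iterates until nothing
#'   changes, which removes branch-free tubes entirely. Typical 50--Inf.
#' @slot overlap minimum number of skeleton pixels an object must contain to
#'   be counted in the area. Typical 10.
#' @slot radius branch points within this distance (px) are averaged into a
#'   single consolidated node. Typical 30--150.
#'
#' @seealso [parameterProfile()], [saveProfile()], [loadProfile()]
#' @export
setClass("ParameterProfile",
  representation(
    scale = "numeric", cannyConnect = "numeric", dilate = "numeric",
    fill = "numeric", clean = "numeric", clip = "numeric",
    overlap = "numeric", radius = "numeric"
  )
)

setValidity("ParameterProfile", function(object) {
  msgs <- character()
  chk1 <- function(x, nm) {
    if (length(x) != 1 || is.na(x)) msgs <<- c(msgs, paste0(nm, " must be a single non-missing value"))
  }
  for (nm in c("scale", "cannyConnect", "dilate", "fill", "clean", "clip",
               "overlap", "radius")) chk1(slot(object, nm), nm)
  if (length(msgs)) return(msgs)
  if (!is.finite(object@scale) || object@scale <= 0)
    msgs <- c(msgs, "scale must be a finite value > 0 (microns per pixel)")
  for (nm in c("cannyConnect", "dilate", "fill", "clean", "overlap", "radius")) {
    v <- slot(object, nm)
    if (!is.finite(v) || v < 0 || v != round(v))
      msgs <- c(msgs, paste0(nm, " must be a non-negative integer (pixels)"))
  }
  if (is.na(object@clip) || object@clip < 0 ||
      (is.finite(object@clip) && object@clip != round(object@clip)))
    msgs <- c(msgs, "clip must be a non-negative integer number of pixels, or Inf")
  if (length(msgs)) msgs else TRUE
})

#' Grayscale image with its source luminance range
#'
#' The channel-mean of an RGB image, linearly stretched so that its minimum
#' and maximum equal the global intensity range of the source image.
#'
#' @slot intensity numeric matrix of pixel intensities (rows x cols).
#' @slot luminanceRange length-2 numeric, the (min, max) intensity of the
#'   source image that the stretch targets.
#' @export
setClass("GrayImage",
  representation(intensity = "matrix", luminanceRange = "numeric")
)

setValidity("GrayImage", function(object) {
  if (!is.numeric(object@intensity)) return("intensity must be numeric")
  if (any(object@intensity < 0)) return("intensities must be non-negative")
  if (length(object@luminanceRange) != 2) return("luminanceRange must have length 2")
  TRUE
})

#' Binary mask of detected tube-like structures
#'
#' Output of the tube-detection stage: edges found by the Canny method,
#' bridged and closed, holes filled, specks cleaned. \code{provenance} records
#' the processing steps applied, in order.
#'
#' @slot mask logical matrix; \code{TRUE} marks detected tube area.
#' @slot provenance character vector of applied step names.
#' @seealso [detectTubes()]
#' @export
setClass("EdgeMask",
  representation(mask = "matrix", provenance = "character")
)

#' One-pixel-wide tube backbone
#'
#' Result of topology-preserving thinning of an [EdgeMask-class]: every
#' object is eroded to a single-pixel-wide backbone without splitting or
#' merging objects (the Euler characteristic is preserved).
#'
#' @slot mask logical matrix; \code{TRUE} marks backbone pixels.
#' @seealso [skeletonize()], [clipSpurs()]
#' @export
setClass("SkeletonMask", representation(mask = "matrix"))

.validity_binary <- function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
}
setValidity("EdgeMask", .validity_binary)
setValidity("SkeletonMask", .validity_binary)

#' Morphometric summary of one analyzed image
#'
#' @slot totalLength total tube length in microns.
#' @slot totalArea total tube area in square microns.
#' @slot nBranchPoints number of consolidated branch points (nodes).
#' @slot avgThickness average tube thickness in microns (area / length);
#'   \code{NA} when length is zero but area is not.
#' @slot sourceFile name of the analyzed file ("" for in-memory analyses).
#' @export
setClass("TubeMetrics",
  representation(
    totalLength = "numeric", totalArea = "numeric",
    nBranchPoints = "numeric", avgThickness = "numeric",
    sourceFile = "character"
  )
)

setValidity("TubeMetrics", function(object) {
  v <- c(object@totalLength, object@totalArea, object@nBranchPoints)
  if (anyNA(v) || any(v < 0)) return("length, area and branch count must be non-negative")
  if (!is.na(object@avgThickness) && object@avgThickness < 0)
    return("avgThickness must be non-negative")
  if (object@totalLength > 0) {
    if (is.na(object@avgThickness))
      return("avgThickness must be defined when totalLength > 0")
    err <- abs(object@avgThickness * object@totalLength - object@totalArea)
    if (err > 1e-6 * max(1, object@totalArea))
      return("avgThickness x totalLength must equal totalArea")
  }
  TRUE
})

#' Specification of a synthetic phantom image
#'
#' A phantom is a set of straight strokes (capsules: all pixels within
#' \code{strokeWidth / 2} of a segment) rasterized without anti-aliasing,
#' optionally corrupted with salt-and-pepper noise. Because a capsule's
#' medial axis is exactly its generating segment, the analytic segment
#' lengths are the ground truth the skeleton should recover.
#'
#' @slot segments numeric matrix with columns \code{r0, c0, r1, c1}
#'   (endpoints in pixel coordinates), one row per stroke; may have 0 rows.
#' @slot strokeWidth stroke width in pixels (>= 1).
#' @slot imageSize integer (height, width).
#' @slot noise salt-and-pepper density in [0, 1).
#' @slot background,foreground intensity levels (0--255).
#' @seealso [phantomSpec()], [renderPhantom()]
#' @export
setClass("PhantomSpec",
  representation(
    segments = "matrix", strokeWidth = "numeric", imageSize = "numeric",
    noise = "numeric", background = "numeric", foreground = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  s <- object@segments
  if (ncol(s) != 4 && nrow(s) > 0) return("segments must have 4 columns (r0, c0, r1, c1)")
  if (object@strokeWidth < 1) return("strokeWidth must be >= 1")
  if (length(object@imageSize) != 2 || any(object@imageSize < 1))
    return("imageSize must be (height, width), both >= 1")
  if (nrow(s) > 0) {
    r <- c(s[, 1], s[, 3]); cc <- c(s[, 2], s[, 4])
    if (any(r < 1) || any(r > object@imageSize[1]) ||
        any(cc < 1) || any(cc > object@imageSize[2]))
      return("all segment endpoints must lie inside the image")
  }
  if (object@noise < 0 || object@noise >= 1) return("noise must be in [0, 1)")
  TRUE
})

#' Analytic ground truth of a phantom
#'
#' @slot totalLength sum of segment Euclidean lengths, in microns.
#' @slot nJunctions number of points where three or more stroke directions
#'   meet (crossings and shared endpoints), after merging junctions closer
#'   than the node-consolidation radius.
#' @slot totalArea rasterized stroke area in square microns.
#' @export
setClass("GroundTruth",
  representation(totalLength = "numeric", nJunctions = "numeric",
                 totalArea = "numeric")
)

#' Record of one image analysis
#'
#' @slot sourceFile analyzed file name.
#' @slot metrics a [TubeMetrics-class].
#' @slot profile the [ParameterProfile-class] used.
#' @slot outputsWritten character vector of overlay files written (empty
#'   when image saving is off).
#' @slot error error message if the image failed, otherwise "".
#' @export
setClass("AnalysisRecord",
  representation(
    sourceFile = "character", metrics = "TubeMetrics",
    profile = "ParameterProfile", outputsWritten = "character",
    error = "character"
  )
)
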