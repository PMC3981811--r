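#' Canny edge detection
#'
#' Finds pixels of high spatial intensity derivative: the image is smoothed
#' with a Gaussian, Sobel gradients are taken, ridge pixels are kept by
#' non-maximum suppression along the gradient direction, and hysteresis
#' linking retains weak edge pixels only when their component contains a
#' strong one. The hysteresis thresholds are derived automatically from the
#' gradient-magnitude histogram (Otsu high threshold, low = \code{lowRatio}
#' x high), so no per-image intensity threshold is needed.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param sigma Gaussian smoothing scale in pixels (default 2).
#' @param lowRatio low/high hysteresis threshold ratio (default 0.4).
#' @return logical matrix of edge pixels, same size as the input.
#' @examples
#' m <- matrix(0, 40, 40); m[10:30, 10:30] <- 200
#' sum(cannyEdges(m))         # edge ring around the square
#' sum(cannyEdges(matrix(5, 20, 20)))   # constant image: no edges
#' @export
cannyEdges <- function(img, sigma = 2, lowRatio = 0.4) {
  x <- .as_intensity(img)
  if (diff(range(x)) == 0) return(matrix(FALSE, nrow(x), ncol(x)))
  g <- EBImage::gblur(x, sigma = sigma, boundary = "replicate")
  kr <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)  # d/drow
  kc <- t(kr)                                                        # d/dcol
  gr <- EBImage::filter2(g, kr, boundary = "replicate")
  gc <- EBImage::filter2(g, kc, boundary = "replicate")
  mag <- sqrt(gr^2 + gc^2)
  mmax <- max(mag)
  if (mmax <= 0) return(matrix(FALSE, nrow(x), ncol(x)))
  keep <- .nms(mag, gr, gc)
  hi <- EBImage::otsu(mag / mmax, range = c(0, 1)) * mmax
  lo <- lowRatio * hi
  weak <- keep & (mag >= lo)
  strong <- keep & (mag >= hi)
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  lab <- .label_components(weak, 8L)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good, nrow(lab), ncol(lab))
}

#' Bridge nearby edge points and close the mask
#'
#' Connects detected edge points lying within \code{cannyConnect} pixels of
#' each other into one object (morphological closing with a disc of that
#' radius), then applies a second closing with a disc of radius
#' \code{dilate} to merge nearby objects. Monotone: the output is a superset
#' of the input foreground.
#'
#' @param edges logical matrix of edge pixels.
#' @param cannyConnect,dilate closing radii in pixels (0 = skip).
#' @return logical matrix.
#' @export
bridgeAndClose <- function(edges, cannyConnect, dilate) {
  m <- .as_mask(edges)
  m <- .disc_close(m, cannyConnect)
  .disc_close(m, dilate)
}

#' Fill small enclosed holes
#'
#' Background regions completely surrounded by foreground whose area is
#' strictly smaller than \code{fill} pixels are filled in (false-negative
#' interior gaps). Enclosed holes of area >= \code{fill} and the unbounded
#' background are untouched. Idempotent. Holes are 4-connected background
#' components, the topological dual of the 8-connected foreground; with an
#' 8-connected background a hole bounded by a thin diagonal edge chain would
#' leak out between its pixels and nothing inside a Canny ring could ever be
#' filled.
#'
#' @param m logical matrix.
#' @param fill area threshold in pixels.
#' @return logical matrix.
#' @export
fillHoles <- function(m, fill) {
  m <- .as_mask(m)
  if (fill <= 0) return(m)
  bg <- .label_components(!m, 4L)
  if (max(bg) == 0L) return(m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  areas <- .component_areas(bg)
  fillable <- setdiff(which(areas < fill), border)
  if (length(fillable)) m[bg %in% fillable] <- TRUE
  m
}

#' Clear small foreground specks
#'
#' Removes every foreground connected component whose area is strictly
#' smaller than \code{clean} pixels (false-positive debris). Idempotent and
#' monotone in the threshold.
#'
#' @param m logical matrix.
#' @param clean area threshold in pixels.
#' @return logical matrix.
#' @export
cleanSpecks <- function(m, clean) {
  m <- .as_mask(m)
  if (clean <= 0) return(m)
  lab <- .label_components(m, 8L)
  if (max(lab) == 0L) return(m)
  areas <- .component_areas(lab)
  small <- which(areas < clean)
  if (length(small)) m[lab %in% small] <- FALSE
  m
}

#' Detect tube-like structures in a grayscale image
#'
#' The full tube-detection stage: Canny edges, optional restriction to a
#' region of interest, bridging/closing, hole filling and speck cleaning, in
#' that order. The returned [EdgeMask-class] records the applied steps in
#' its provenance, and its foreground never extends outside \code{roi}.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param profile a [ParameterProfile-class].
#' @param roi optional logical matrix of the same size; detection is
#'   restricted to its \code{TRUE} region (e.g. the non-black area of a
#'   retinal fundus photograph).
#' @param sigma,lowRatio advanced Canny settings, see [cannyEdges()].
#' @return an [EdgeMask-class].
#' @seealso [skeletonize()], [analyzeImage()]
#' @export
detectTubes <- function(img, profile, roi = NULL, sigma = 2, lowRatio = 0.4) {
  stopifnot(is(profile, "ParameterProfile"))
  validObject(profile)
  x <- .as_intensity(img)
  steps <- "canny"
  m <- cannyEdges(x, sigma = sigma, lowRatio = lowRatio)
  if (!is.null(roi)) {
    roi <- .as_mask(roi)
    if (!all(dim(roi) == dim(x)))
      .tm_error(sprintf("roi dimensions (%d x %d) do not match image (%d x %d)",
                        nrow(roi), ncol(roi), nrow(x), ncol(x)),
                "tubemorph_dim_mismatch")
    m <- m & roi
    steps <- c(steps, "roi")
  }
  m <- bridgeAndClose(m, profile@cannyConnect, profile@dilate)
  steps <- c(steps, "bridge", "close")
  m <- fillHoles(m, profile@fill)
  steps <- c(steps, "fill")
  m <- cleanSpecks(m, profile@clean)
  steps <- c(steps, "clean")
  if (!is.null(roi)) m <- m & roi   # closing must not leak outside the roi
  new("EdgeMask", mask = m, provenance = steps)
}
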