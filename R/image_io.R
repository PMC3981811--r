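#' Load a TIFF image as an RGB array
#'
#' Reads a bright-field TIFF and returns a height x width x 3 numeric array
#' (red, green, blue planes) on the stored integer scale (0--255 for 8-bit
#' input). Grayscale TIFFs are promoted to three identical planes; an alpha
#' channel, if present, is dropped. No lossy re-encoding is applied.
#'
#' TIFF is required in strict mode: lossy-compressed formats blunt the
#' high-frequency intensity changes the edge detector relies on. With
#' \code{strict = FALSE}, PNG is also accepted (useful for testing).
#'
#' @param path path to the image file.
#' @param strict if \code{TRUE} (default) only TIFF input is accepted.
#' @return numeric array \code{c(height, width, 3)}.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writePhantomTIFF(renderPhantom(phantomSpec(
#'   segments = rbind(c(20, 10, 20, 50)), imageSize = c(40, 60)))$image, f)
#' img <- loadImage(f)
#' dim(img)
#' @export
loadImage <- function(path, strict = TRUE) {
  if (!file.exists(path))
    .tm_error(paste0("image file not found: ", path), "tubemorph_not_found")
  raw <- tryCatch(suppressWarnings(tiff::readTIFF(path, info = TRUE)),
                  error = function(e) NULL)
  if (!is.null(raw)) {
    # readTIFF rescales to [0, 1]; restore the stored integer scale
    bits <- attr(raw, "bits.per.sample")[1]
    if (is.null(bits) || !is.numeric(bits) || is.na(bits)) bits <- 8L
    raw <- round(unclass(raw) * (2^bits - 1))
  }
  if (is.null(raw) && !strict && requireNamespace("png", quietly = TRUE)) {
    p <- tryCatch(png::readPNG(path), error = function(e) NULL)
    if (!is.null(p)) raw <- round(p * 255)
  }
  if (is.null(raw))
    .tm_error(paste0("unsupported or corrupt image format (TIFF required): ", path),
              "tubemorph_bad_format")
  attributes(raw) <- list(dim = dim(raw))
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  if (dim(raw)[3] >= 3) {
    out <- raw[, , 1:3, drop = FALSE]
  } else {
    out <- array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  }
  storage.mode(out) <- "double"
  out
}

#' Convert an RGB image to grayscale
#'
#' The three channel planes are averaged pixel-wise, and the result is
#' linearly stretched so its minimum and maximum equal the global intensity
#' range of the source image (the "luminosity" of the original). For a
#' zero-dynamic-range source (all pixels equal) the stretch is skipped.
#'
#' @param img numeric array \code{c(h, w, 3)} as returned by [loadImage()].
#' @return a [GrayImage-class].
#' @examples
#' img <- array(c(30, 60, 90), dim = c(1, 1, 3))   # single pixel
#' toGrayscale(array(rep(128, 12), dim = c(2, 2, 3)))
#' @export
toGrayscale <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  ch <- function(k) matrix(img[, , k], dim(img)[1], dim(img)[2])
  g <- (ch(1) + ch(2) + ch(3)) / 3
  lum <- range(img)
  gr <- range(g)
  if (gr[2] > gr[1] && lum[2] > lum[1]) {
    g <- (g - gr[1]) / (gr[2] - gr[1]) * (lum[2] - lum[1]) + lum[1]
  }
  new("GrayImage", intensity = g, luminanceRange = lum)
}

#' Write a colored mask overlay onto a base image
#'
#' Produces an 8-bit RGB TIFF equal to \code{base} wherever \code{mask} is 0
#' and to \code{color} wherever it is 1, the record-of-analysis images saved
#' alongside batch results.
#'
#' @param base numeric array \code{c(h, w, 3)}, intensities 0--255.
#' @param mask logical matrix (or [EdgeMask-class] / [SkeletonMask-class])
#'   of the same height and width.
#' @param color length-3 RGB triple, 0--255.
#' @param path output TIFF path.
#' @return the output path, invisibly.
#' @export
writeOverlay <- function(base, mask, color, path) {
  m <- .as_mask(mask)
  if (!all(dim(m) == dim(base)[1:2]))
    .tm_error(sprintf("mask dimensions (%d x %d) do not match base (%d x %d)",
                      nrow(m), ncol(m), dim(base)[1], dim(base)[2]),
              "tubemorph_dim_mismatch")
  out <- base
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- color[ch]
    out[, , ch] <- plane
  }
  out <- pmin(pmax(out, 0), 255)
  tiff::writeTIFF(out / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an RGB image (0--255 scale) as an 8-bit TIFF
#'
#' Used to persist rendered phantoms; integer intensities round-trip exactly
#' through [loadImage()].
#'
#' @param img numeric array \code{c(h, w, 3)}, intensities 0--255.
#' @param path output TIFF path.
#' @return the output path, invisibly.
#' @export
writePhantomTIFF <- function(img, path) {
  stopifnot(is.array(img), length(dim(img)) == 3)
  tiff::writeTIFF(pmin(pmax(img, 0), 255) / 255, path, bits.per.sample = 8L)
  invisible(path)
}
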