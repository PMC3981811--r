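#' Create a phantom specification
#'
#' @param segments numeric matrix with columns \code{r0, c0, r1, c1}, one
#'   stroke per row (0 rows for a blank control).
#' @param strokeWidth stroke width in pixels.
#' @param imageSize (height, width) in pixels.
#' @param noise salt-and-pepper density in [0, 1).
#' @param background,foreground intensity levels, 0--255. The defaults are a
#'   light background with dark strokes, the polarity of bright-field tube
#'   images (edge detection is polarity-blind).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(segments, strokeWidth = 5, imageSize = c(512, 512),
                        noise = 0, background = 200, foreground = 40) {
  if (is.null(segments) || length(segments) == 0)
    segments <- matrix(numeric(0), 0, 4)
  segments <- as.matrix(segments)
  colnames(segments) <- c("r0", "c0", "r1", "c1")
  new("PhantomSpec", segments = segments, strokeWidth = strokeWidth,
      imageSize = imageSize, noise = noise,
      background = background, foreground = foreground)
}

# segments of a polyline given its vertex matrix (r, c)
.poly_segments <- function(pts) {
  n <- nrow(pts)
  cbind(pts[-n, 1], pts[-n, 2], pts[-1, 1], pts[-1, 2])
}

# distances from points (r, c vectors) to segment (r0, c0)-(r1, c1)
.seg_dist <- function(r, c, s) {
  dr <- s[3] - s[1]; dc <- s[4] - s[2]
  len2 <- dr^2 + dc^2
  if (len2 == 0) return(sqrt((r - s[1])^2 + (c - s[2])^2))
  t <- pmin(pmax(((r - s[1]) * dr + (c - s[2]) * dc) / len2, 0), 1)
  sqrt((r - (s[1] + t * dr))^2 + (c - (s[2] + t * dc))^2)
}

# ground-truth junctions: points where >= 3 stroke directions meet
# (crossings count each passing segment twice, a terminating segment once);
# junctions closer than mergeRadius are counted once, mirroring node
# consolidation.
.phantom_junctions <- function(segments, mergeRadius = 30, tol = 1e-6) {
  if (nrow(segments) < 2) return(0L)
  pts <- NULL
  n <- nrow(segments)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- segments[i, ]; b <- segments[j, ]
      d1r <- a[3] - a[1]; d1c <- a[4] - a[2]
      d2r <- b[3] - b[1]; d2c <- b[4] - b[2]
      den <- d1r * d2c - d1c * d2r
      if (abs(den) < tol) next              # parallel or collinear: no crossing
      t <- ((b[1] - a[1]) * d2c - (b[2] - a[2]) * d2r) / den
      u <- ((b[1] - a[1]) * d1c - (b[2] - a[2]) * d1r) / den
      eps <- 1e-9
      if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) next
      pts <- rbind(pts, c(a[1] + t * d1r, a[2] + t * d1c))
    }
  }
  if (is.null(pts)) return(0L)
  # deduplicate candidate points
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      d <- sqrt((pts[-(1:i), 1] - pts[i, 1])^2 + (pts[-(1:i), 2] - pts[i, 2])^2)
      keep[(i + 1):nrow(pts)][d < 0.5] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  # degree at each candidate: 2 per segment passing through, 1 per segment
  # terminating there
  degree <- vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]; deg <- 0L
    for (i in seq_len(n)) {
      s <- segments[i, ]
      if (.seg_dist(p[1], p[2], s) > 0.5) next
      at_end <- min(sqrt((p[1] - s[1])^2 + (p[2] - s[2])^2),
                    sqrt((p[1] - s[3])^2 + (p[2] - s[4])^2)) < 0.5
      deg <- deg + if (at_end) 1L else 2L
    }
    deg
  }, integer(1))
  junc <- pts[degree >= 3L, , drop = FALSE]
  if (nrow(junc) == 0) return(0L)
  if (nrow(junc) == 1) return(1L)
  cl <- stats::cutree(stats::hclust(stats::dist(junc), method = "single"),
                      h = mergeRadius)
  length(unique(cl))
}

#' Render a phantom image with analytic ground truth
#'
#' Rasterizes each stroke as a capsule (every pixel centre within
#' \code{strokeWidth / 2} of the segment), with hard edges and no
#' anti-aliasing, so phantom tubes present strong intensity gradients like
#' real tube borders. A capsule's medial axis is exactly its generating
#' segment, so the analytic segment lengths are the truth the skeleton
#' should recover. Ground truth is computed from the geometry (length,
#' junctions) and the rasterized stroke mask (area), never from a
#' measurement, making it an independent oracle for the pipeline. Rendering
#' is deterministic: identical spec and seed give identical output.
#'
#' @param spec a [PhantomSpec-class].
#' @param scale microns per pixel used to express the truth.
#' @param mergeRadius junctions closer than this are counted once (match the
#'   node-consolidation radius of the analysis profile).
#' @param seed RNG seed for the salt-and-pepper noise, when
#'   \code{spec@noise > 0}.
#' @return list with \code{image} (h x w x 3 array, 0--255), \code{truth}
#'   (a [GroundTruth-class]) and \code{mask} (the logical stroke raster).
#' @examples
#' ph <- renderPhantom(phantomSpec(rbind(c(30, 10, 30, 90)),
#'                                 imageSize = c(60, 100)))
#' totalLength(ph$truth)   # 80: analytic segment length
#' @export
renderPhantom <- function(spec, scale = 1, mergeRadius = 30, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@imageSize[1]; w <- spec@imageSize[2]
  mask <- matrix(FALSE, h, w)
  half <- spec@strokeWidth / 2
  for (i in seq_len(nrow(spec@segments))) {
    s <- spec@segments[i, ]
    r0 <- max(1, floor(min(s[1], s[3]) - half - 1))
    r1 <- min(h, ceiling(max(s[1], s[3]) + half + 1))
    c0 <- max(1, floor(min(s[2], s[4]) - half - 1))
    c1 <- min(w, ceiling(max(s[2], s[4]) + half + 1))
    rr <- r0:r1; cc <- c0:c1
    d <- .seg_dist(rep(rr, times = length(cc)), rep(cc, each = length(rr)), s)
    mask[rr, cc] <- mask[rr, cc] | (matrix(d, length(rr), length(cc)) <= half)
  }
  seglen <- if (nrow(spec@segments)) {
    sum(sqrt((spec@segments[, 3] - spec@segments[, 1])^2 +
             (spec@segments[, 4] - spec@segments[, 2])^2))
  } else 0
  truth <- new("GroundTruth",
               totalLength = seglen * scale,
               nJunctions = as.numeric(.phantom_junctions(spec@segments, mergeRadius)),
               totalArea = sum(mask) * scale^2)
  plane <- matrix(spec@background, h, w)
  plane[mask] <- spec@foreground
  img <- array(plane, dim = c(h, w, 3))
  if (spec@noise > 0) img <- addSaltPepper(img, spec@noise, seed)
  list(image = img, truth = truth, mask = mask)
}

#' Add salt-and-pepper noise
#'
#' Each pixel is independently flipped, with probability \code{density}, to
#' the minimum or maximum intensity (0 or 255; half salt, half pepper),
#' across all three channels. Reproducible for a fixed seed; the caller's
#' RNG stream is left untouched.
#'
#' @param img numeric array \code{c(h, w, 3)}, 0--255.
#' @param density flip probability in [0, 1).
#' @param seed integer RNG seed.
#' @return the noisy image array.
#' @export
addSaltPepper <- function(img, density, seed = 1L) {
  stopifnot(density >= 0, density < 1)
  if (density == 0) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  .with_seed(seed, {
    u <- matrix(stats::runif(h * w), h, w)
    salt <- matrix(stats::runif(h * w) < 0.5, h, w)
    flip <- u < density
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[flip & salt] <- 255
      plane[flip & !salt] <- 0
      img[, , ch] <- plane
    }
  })
  img
}

#' Add a linear illumination gradient
#'
#' Overlays a linear intensity ramp across the image, emulating the uneven
#' background brightness of a non-flat gel surface. Useful for checking that
#' edge-based detection, unlike global thresholding, tolerates smooth
#' illumination drift. Off by default in all generators.
#'
#' @param img numeric array \code{c(h, w, 3)}, 0--255.
#' @param amplitude total intensity change from one image side to the other.
#' @param direction \code{"horizontal"} (along columns) or \code{"vertical"}.
#' @return the image with the ramp added, clamped to 0--255.
#' @export
addIlluminationGradient <- function(img, amplitude = 30,
                                    direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  h <- dim(img)[1]; w <- dim(img)[2]
  ramp <- if (direction == "horizontal")
    matrix(seq(0, amplitude, length.out = w), h, w, byrow = TRUE)
  else
    matrix(seq(0, amplitude, length.out = h), h, w)
  for (ch in 1:3) img[, , ch] <- pmin(pmax(img[, , ch] + ramp, 0), 255)
  img
}

#' Deterministic in-silico validation suite
#'
#' Renders a battery of >= 20 phantom archetypes with analytic ground truth:
#' straight and 45-degree-rotated lines, T/Y/X junctions, a plus, parallel
#' lines, 2x2 and 3x3 grids, an H, a ladder, a comb, a closed loop, a
#' chevron, a staircase curve and a blank control, plus salt-and-pepper-noise
#' variants (flagged by \code{noise > 0}). Stroke orientations are
#' restricted to multiples of 45 degrees, where the (1, 1.414) adjacency
#' length weighting is exact. All junctions are spaced farther apart than
#' the consolidation radius, so the analytic junction count equals the
#' expected consolidated node count.
#'
#' @param scale microns per pixel for the ground truth.
#' @param seed integer seed for the noisy variants.
#' @param strokeWidth stroke width in pixels.
#' @param mergeRadius junction merge radius, see [renderPhantom()].
#' @return named list of entries, each a list with \code{name}, \code{spec},
#'   \code{image}, \code{truth}, \code{mask} and \code{noise}.
#' @export
validationSuite <- function(scale = 1, seed = 1L, strokeWidth = 5,
                            mergeRadius = 30) {
  S <- function(...) rbind(...)
  d45 <- 400 / (2 * sqrt(2))   # half-extent of a length-400 diagonal
  geoms <- list(
    blank      = NULL,
    hline      = S(c(256, 56, 256, 456)),
    vline      = S(c(56, 256, 456, 256)),
    diag45     = S(c(256 - d45, 256 - d45, 256 + d45, 256 + d45)),
    diag135    = S(c(256 - d45, 256 + d45, 256 + d45, 256 - d45)),
    diag_short = S(c(150, 100, 362, 312)),
    lshape     = .poly_segments(S(c(400, 100), c(150, 100), c(150, 350))),
    tee        = S(c(256, 76, 256, 436), c(256, 256, 436, 256)),
    wye        = S(c(200, 256, 60, 256), c(200, 256, 340, 116),
                   c(200, 256, 340, 396)),
    cross      = S(c(116, 116, 396, 396), c(116, 396, 396, 116)),
    plus       = S(c(256, 76, 256, 436), c(76, 256, 436, 256)),
    parallel   = S(c(200, 76, 200, 436), c(312, 76, 312, 436)),
    grid2      = S(c(180, 100, 180, 412), c(332, 100, 332, 412),
                   c(100, 180, 412, 180), c(100, 332, 412, 332)),
    grid3      = S(c(128, 64, 128, 448), c(256, 64, 256, 448), c(384, 64, 384, 448),
                   c(64, 128, 448, 128), c(64, 256, 448, 256), c(64, 384, 448, 384)),
    hshape     = S(c(136, 186, 376, 186), c(136, 326, 376, 326),
                   c(256, 186, 256, 326)),
    chevron    = .poly_segments(S(c(440, 64), c(260, 244), c(440, 424))),
    curve      = .poly_segments(S(c(380, 100), c(380, 180), c(300, 260),
                                  c(220, 260), c(140, 340))),
    double_tee = S(c(100, 76, 100, 436), c(100, 156, 300, 156),
                   c(100, 356, 300, 356)),
    comb       = S(c(400, 76, 400, 436), c(240, 166, 400, 166),
                   c(240, 256, 400, 256), c(240, 346, 400, 346)),
    double_x   = S(c(100, 60, 220, 180), c(220, 60, 100, 180),
                   c(340, 300, 460, 420), c(460, 300, 340, 420)),
    ladder     = S(c(116, 196, 396, 196), c(116, 316, 396, 316),
                   c(156, 196, 156, 316), c(256, 196, 256, 316),
                   c(356, 196, 356, 316)),
    loop       = .poly_segments(S(c(156, 156), c(156, 356), c(356, 356),
                                  c(356, 156), c(156, 156)))
  )
  noisy <- c("hline", "cross", "grid2")
  out <- list()
  for (nm in names(geoms)) {
    sp <- phantomSpec(geoms[[nm]], strokeWidth = strokeWidth)
    ph <- renderPhantom(sp, scale = scale, mergeRadius = mergeRadius)
    out[[nm]] <- list(name = nm, spec = sp, image = ph$image,
                      truth = ph$truth, mask = ph$mask, noise = 0)
  }
  for (i in seq_along(noisy)) {
    nm <- noisy[i]
    sp <- phantomSpec(geoms[[nm]], strokeWidth = strokeWidth, noise = 0.02)
    ph <- renderPhantom(sp, scale = scale, mergeRadius = mergeRadius,
                        seed = seed + i)
    key <- paste0("noisy_", nm)
    out[[key]] <- list(name = key, spec = sp, image = ph$image,
                       truth = ph$truth, mask = ph$mask, noise = 0.02)
  }
  out
}

#' Write the validation suite to disk
#'
#' Saves every suite image as an 8-bit TIFF plus a \code{ground_truth.csv}
#' with columns \code{file, length_um, junctions, area_um2, noise}.
#'
#' @param outDir output directory (created if needed).
#' @inheritParams validationSuite
#' @return path of the ground-truth CSV, invisibly.
#' @export
writeValidationSuite <- function(outDir, scale = 1, seed = 1L,
                                 strokeWidth = 5, mergeRadius = 30) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  suite <- validationSuite(scale, seed, strokeWidth, mergeRadius)
  rows <- lapply(suite, function(e) {
    f <- paste0(e$name, ".tif")
    writePhantomTIFF(e$image, file.path(outDir, f))
    data.frame(file = f, length_um = totalLength(e$truth),
               junctions = nBranchPoints(e$truth),
               area_um2 = totalArea(e$truth), noise = e$noise)
  })
  csv <- file.path(outDir, "ground_truth.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}
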