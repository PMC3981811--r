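# internal helpers shared across modules

.tm_error <- function(msg, class) {
  stop(structure(
    class = c(class, "tubemorph_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# coerce GrayImage / logical matrix / numeric matrix to a numeric matrix
.as_intensity <- function(x) {
  if (is(x, "GrayImage")) return(x@intensity)
  if (is.matrix(x)) return(x * 1.0)
  stop("expected a GrayImage or a matrix")
}

.as_mask <- function(x) {
  if (is(x, "EdgeMask") || is(x, "SkeletonMask")) return(x@mask)
  if (is.matrix(x)) {
    m <- x != 0
    m[is.na(m)] <- FALSE
    return(m)
  }
  stop("expected an EdgeMask, SkeletonMask or matrix")
}

# morphological closing with a disc of the given radius; r = 0 is identity
.disc_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::erode(EBImage::dilate(mask * 1, brush), brush)
  out > 0
}

.disc_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(mask * 1, brush) > 0
}

# erosion that treats everything beyond the image border as background, so
# a mask touching the border loses its rim there too
.disc_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- as.integer(radius)
  padded <- matrix(FALSE, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  padded[(r + 1):(r + nrow(mask)), (r + 1):(r + ncol(mask))] <- mask
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  out <- EBImage::erode(padded * 1, brush) > 0
  out[(r + 1):(r + nrow(mask)), (r + 1):(r + ncol(mask))]
}

# component areas keyed by label (0 excluded)
.component_areas <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  tab
}

# run code with a temporarily-seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
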