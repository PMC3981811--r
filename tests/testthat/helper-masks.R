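# fixture builders used across test files (everything generated in code)

# hollow rectangular ring whose enclosed hole has exactly hole_h x hole_w px
ring_mask <- function(hole_h, hole_w, thickness = 1) {
  h <- hole_h + 2 * thickness
  w <- hole_w + 2 * thickness
  m <- matrix(TRUE, h, w)
  m[(thickness + 1):(thickness + hole_h), (thickness + 1):(thickness + hole_w)] <- FALSE
  m
}

# place a small mask inside a larger all-background canvas at (r, c)
place <- function(canvas, block, r, c) {
  canvas[r:(r + nrow(block) - 1), c:(c + ncol(block) - 1)] <-
    canvas[r:(r + nrow(block) - 1), c:(c + ncol(block) - 1)] | block
  canvas
}

# straight skeleton path of n pixels along a row
path_mask <- function(n, nrow = 7, pad = 3) {
  m <- matrix(FALSE, nrow, n + 2 * pad)
  m[ceiling(nrow / 2), (pad + 1):(pad + n)] <- TRUE
  m
}

# plus-shaped skeleton: 4 arms of arm_len pixels around a centre pixel
plus_mask <- function(arm_len, pad = 3) {
  n <- 2 * arm_len + 1 + 2 * pad
  ctr <- pad + arm_len + 1
  m <- matrix(FALSE, n, n)
  m[ctr, (ctr - arm_len):(ctr + arm_len)] <- TRUE
  m[(ctr - arm_len):(ctr + arm_len), ctr] <- TRUE
  m
}

n_components <- function(m) max(tubemorph:::.label_components(m, 8L), 0L)

# a small single-bar phantom (capsule) for pipeline-level tests
bar_phantom <- function(len = 100, width = 5, size = c(160, 160), noise = 0) {
  r <- size[1] / 2
  c0 <- (size[2] - len) / 2
  phantomSpec(rbind(c(r, c0, r, c0 + len)), strokeWidth = width,
              imageSize = size, noise = noise)
}

write_tiff_phantom <- function(spec, dir = tempdir(), name = "phantom.tif",
                               seed = 1L) {
  ph <- renderPhantom(spec, seed = seed)
  path <- file.path(dir, name)
  writePhantomTIFF(ph$image, path)
  list(path = path, truth = ph$truth, mask = ph$mask, image = ph$image)
}
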