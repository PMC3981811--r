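test_that("Canny finds edges at object boundaries and nothing in flat images", {
  expect_false(any(cannyEdges(matrix(7, 30, 30))))

  # bright 20x20 square: every edge pixel lies within 3 px of the true boundary
  m <- matrix(0, 60, 60)
  m[21:40, 21:40] <- 200
  e <- cannyEdges(m)
  expect_gt(sum(e), 0)
  idx <- which(e, arr.ind = TRUE)
  # unsigned distance to the boundary of the square [21, 40] x [21, 40]
  dist_box <- function(r, c) {
    dr <- pmax(21 - r, 0, r - 40); dc <- pmax(21 - c, 0, c - 40)
    outside <- sqrt(dr^2 + dc^2)
    inside <- pmin(r - 21, 40 - r, c - 21, 40 - c)
    ifelse(dr > 0 | dc > 0, outside, inside)
  }
  expect_lte(max(dist_box(idx[, 1], idx[, 2])), 3)

  # phantom tube: > 95% of edge pixels within the dilated true stroke region
  ph <- renderPhantom(bar_phantom(len = 100, width = 5))
  e2 <- cannyEdges(intensity(toGrayscale(ph$image)))
  halo <- tubemorph:::.disc_dilate(ph$mask, 3)
  expect_gt(sum(e2 & halo) / sum(e2), 0.95)
})

test_that("bridging connects points within reach and leaves distant ones apart", {
  m <- matrix(FALSE, 20, 20); m[10, 5] <- TRUE; m[10, 8] <- TRUE  # 3 px apart
  out <- bridgeAndClose(m, cannyConnect = 4, dilate = 0)
  expect_identical(n_components(out), 1L)
  expect_true(all(out[m]))   # superset of the input

  m2 <- matrix(FALSE, 30, 80); m2[15, 10] <- TRUE; m2[15, 60] <- TRUE  # 50 apart
  expect_identical(n_components(bridgeAndClose(m2, 4, 2)), 2L)

  # dashed line with 4-px gaps becomes one object of about the solid length
  dash <- matrix(FALSE, 15, 120)
  for (s in seq(10, 100, by = 10)) dash[8, s:(s + 5)] <- TRUE
  closed <- bridgeAndClose(dash, 4, 0)
  expect_identical(n_components(closed), 1L)
  len <- measureLength(maskMatrix(skeletonize(closed)), 1)
  expect_gt(len, 0.9 * 95)
})

test_that("hole filling is strict in area and ignores unbounded background", {
  # 3x3 hole (9 px) < fill: becomes solid
  solid <- fillHoles(ring_mask(3, 3), 200)
  expect_true(all(solid))

  # 6000-px hole >= fill: unchanged
  big <- ring_mask(60, 100)
  expect_identical(fillHoles(big, 200), big)

  # holes {10, 150, 250} with fill = 200: exactly the 10 and 150 are filled
  canvas <- matrix(FALSE, 60, 120)
  canvas <- place(canvas, ring_mask(2, 5), 5, 5)       # 10-px hole
  canvas <- place(canvas, ring_mask(10, 15), 5, 40)    # 150-px hole
  canvas <- place(canvas, ring_mask(10, 25), 30, 40)   # 250-px hole
  before <- sum(canvas)
  after <- fillHoles(canvas, 200)
  expect_identical(sum(after), before + 10L + 150L)
  expect_identical(fillHoles(after, 200), after)       # idempotent
})

test_that("speck cleaning removes components strictly smaller than the threshold", {
  canvas <- matrix(FALSE, 120, 260)
  canvas <- place(canvas, matrix(TRUE, 20, 25), 2, 2)     # 500
  canvas <- place(canvas, matrix(TRUE, 27, 37), 2, 60)    # 999
  canvas <- place(canvas, matrix(TRUE, 25, 40), 2, 120)   # 1000
  canvas <- place(canvas, matrix(TRUE, 50, 80), 60, 120)  # 4000
  out <- cleanSpecks(canvas, 1000)
  expect_identical(n_components(out), 2L)
  expect_identical(sum(out), 1000L + 4000L)

  # trivial cases
  speck <- matrix(FALSE, 10, 10); speck[5, 5] <- TRUE
  expect_false(any(cleanSpecks(speck, 1000)))
  tube <- place(matrix(FALSE, 80, 80), matrix(TRUE, 50, 100)[1:50, 1:70], 5, 5)
  expect_identical(cleanSpecks(tube, 1000), tube)

  # idempotent and monotone in the threshold
  set.seed(21)
  for (i in 1:5) {
    m <- tubemorph:::.disc_dilate(matrix(runif(70 * 70) < 0.02, 70, 70), 2)
    c1 <- cleanSpecks(m, 20); c2 <- cleanSpecks(m, 60)
    expect_identical(cleanSpecks(c1, 20), c1)
    expect_true(all(c1[c2]))   # larger threshold output is a subset
  }
})

test_that("detectTubes composes the stages and honours the roi", {
  prof <- phantomProfile()

  u <- detectTubes(matrix(3, 40, 40), prof)
  expect_false(any(maskMatrix(u)))
  expect_identical(provenance(u)[1], "canny")

  # a single thick tube yields exactly one component after cleanup
  ph <- renderPhantom(bar_phantom(len = 100, width = 5))
  em <- detectTubes(toGrayscale(ph$image), prof)
  expect_identical(n_components(maskMatrix(em)), 1L)

  # roi restriction: nothing detected in the masked-out left half
  roi <- matrix(TRUE, 160, 160); roi[, 1:80] <- FALSE
  em2 <- detectTubes(toGrayscale(ph$image), prof, roi = roi)
  expect_false(any(maskMatrix(em2)[, 1:80]))
  expect_true(all(roi[maskMatrix(em2)]))

  expect_error(detectTubes(toGrayscale(ph$image), prof, roi = matrix(TRUE, 5, 5)),
               class = "tubemorph_dim_mismatch")
})

test_that("detected mask overlaps the true stroke region well on a phantom", {
  # wide stroke so the 1-2 px edge-localization halo stays a small fraction;
  # fill raised to cover the wider bar's interior between its side edges
  ph <- renderPhantom(bar_phantom(len = 100, width = 10, size = c(160, 160)))
  prof <- phantomProfile(); prof@fill <- 2000
  em <- maskMatrix(detectTubes(toGrayscale(ph$image), prof))
  jacc <- sum(em & ph$mask) / sum(em | ph$mask)
  expect_gte(jacc, 0.8)
})
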