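test_that("length weights orthogonal and diagonal adjacencies correctly", {
  # 11-px horizontal line: 10 orthogonal adjacencies
  expect_equal(measureLength(path_mask(11), 1), 10)

  # 11-px perfect diagonal: 10 x 1.414
  expect_equal(measureLength(diag(11) > 0, 1), 14.14)

  # L-shaped path (6 + 6 sharing a corner) at 2 um/px: the corner diagonal
  # is redundant and must not be double-counted
  L <- matrix(FALSE, 10, 10)
  L[8, 2:7] <- TRUE; L[3:8, 7] <- TRUE
  expect_equal(measureLength(L, 2), 20)

  # empty skeleton
  expect_equal(measureLength(matrix(FALSE, 5, 5), 1), 0)

  # linear in scale; invariant under transposition
  set.seed(9)
  m <- maskMatrix(skeletonize(tubemorph:::.disc_dilate(
    matrix(runif(60 * 60) < 0.03, 60, 60), 3)))
  expect_equal(measureLength(m, 3.5), 3.5 * measureLength(m, 1))
  expect_equal(measureLength(t(m), 1), measureLength(m, 1))
})

test_that("branch pixels are skeleton pixels with three or more neighbours", {
  expect_false(any(findBranchPixels(path_mask(15))))

  # plus sign: the centre (4 neighbours) is flagged; the four arm pixels
  # touching it also have >= 3 neighbours, so all raw flags hug the centre
  # and consolidate to a single node
  pl <- plus_mask(5)
  bp <- findBranchPixels(pl)
  ctr <- (nrow(pl) + 1) / 2
  expect_true(bp[ctr, ctr])
  idx <- which(bp, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - ctr) + abs(idx[, 2] - ctr) <= 1))
  expect_identical(nrow(consolidateNodes(bp, 30)), 1L)

  # Y-junction phantom: all flagged pixels near the true junction
  sp <- phantomSpec(rbind(c(40, 80, 110, 80), c(110, 80, 180, 10),
                          c(110, 80, 180, 150)), imageSize = c(200, 160))
  ph <- renderPhantom(sp)
  res <- tubemorph:::.analyze_array(ph$image, phantomProfile())
  bp2 <- which(findBranchPixels(maskMatrix(res$skeleton)), arr.ind = TRUE)
  expect_gte(nrow(bp2), 1)
  d <- sqrt((bp2[, 1] - 110)^2 + (bp2[, 2] - 80)^2)
  expect_true(all(d <= 4))
})

test_that("node consolidation single-links within the radius", {
  m <- matrix(FALSE, 10, 10); m[1, 1] <- TRUE; m[1, 5] <- TRUE
  out <- consolidateNodes(m, 30)
  expect_identical(nrow(out), 1L)
  expect_equal(out$row, 1); expect_equal(out$col, 3)
  expect_identical(out$support, 2L)

  # beyond the radius: two nodes
  m2 <- matrix(FALSE, 20, 250); m2[10, 10] <- TRUE; m2[10, 210] <- TRUE
  expect_identical(nrow(consolidateNodes(m2, 30)), 2L)

  # salt-and-pepper cluster of 7 pixels inside a 10-px disc -> one node
  set.seed(4)
  m3 <- matrix(FALSE, 60, 60)
  ang <- runif(7, 0, 2 * pi); rad <- runif(7, 0, 5)
  m3[cbind(round(30 + rad * sin(ang)), round(30 + rad * cos(ang)))] <- TRUE
  expect_identical(nrow(consolidateNodes(m3, 30)), 1L)

  # empty input and monotonicity in the radius
  expect_identical(nrow(consolidateNodes(matrix(FALSE, 5, 5), 10)), 0L)
  set.seed(14)
  m4 <- matrix(runif(50 * 50) < 0.01, 50, 50)
  counts <- vapply(c(0, 2, 5, 10, 25), function(r) nrow(consolidateNodes(m4, r)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("area counts only components that contribute to the skeleton", {
  canvas <- matrix(FALSE, 140, 210)
  skel <- matrix(FALSE, 140, 210)
  blocks <- list(c(5, 5), c(5, 110), c(75, 5), c(75, 110))
  hits <- c(0, 9, 10, 80)   # skeleton pixels inside each 30x90 block
  for (i in 1:4) {
    at <- blocks[[i]]
    canvas <- place(canvas, matrix(TRUE, 30, 90), at[1], at[2])
    if (hits[i] > 0) skel[at[1] + 15, at[2]:(at[2] + hits[i] - 1)] <- TRUE
  }
  # overlap = 10 keeps exactly the components with >= 10 skeleton pixels
  expect_equal(measureArea(canvas, skel, overlap = 10, scale = 1), 2 * 30 * 90)
  # scale enters quadratically
  expect_equal(measureArea(canvas, skel, 10, scale = 2), 4 * 2 * 30 * 90)
  # overlap 0 keeps every component
  expect_equal(measureArea(canvas, skel, 0, 1), 4 * 30 * 90)
})

test_that("thickness is area over length with sane degenerate behaviour", {
  expect_equal(averageThickness(200, 50), 4)
  expect_equal(averageThickness(0, 0), 0)
  expect_true(is.na(averageThickness(10, 0)))

  # phantom bar of drawn width 20: recovered thickness within 15% of the
  # drawn width (the detected band carries a ~1-px halo per side, so the
  # relative bias shrinks with stroke width) and closer still to the
  # analytic area/length of the capsule; fill raised to cover the bar's
  # interior between its side edges
  ph <- renderPhantom(phantomSpec(rbind(c(70, 30, 70, 430)), strokeWidth = 20,
                                  imageSize = c(140, 460)))
  prof <- phantomProfile(); prof@fill <- 12000
  m <- tubemorph:::.analyze_array(ph$image, prof)$metrics
  expect_lt(abs(avgThickness(m) - 20) / 20, 0.15)
  truthThick <- totalArea(ph$truth) / totalLength(ph$truth)
  expect_lt(abs(avgThickness(m) - truthThick) / truthThick, 0.10)

  # internal consistency: thickness x length = area
  expect_equal(avgThickness(m) * totalLength(m), totalArea(m))
})

test_that("relative percent difference matches its definition and is symmetric", {
  expect_equal(relativePercentDifference(100, 100), 0)
  expect_equal(relativePercentDifference(150, 100), 50)
  expect_true(is.na(relativePercentDifference(0, 0)))
  set.seed(2)
  for (i in 1:10) {
    a <- runif(1, 1, 1000); b <- runif(1, 1, 1000)
    expect_equal(relativePercentDifference(a, b), relativePercentDifference(b, a))
    expect_equal(relativePercentDifference(a, b), abs(a - b) / min(a, b) * 100)
  }
})
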