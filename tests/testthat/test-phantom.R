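test_that("phantom ground truth is analytic and rotation-invariant", {
  # single horizontal 100-px segment at width 5
  sp <- phantomSpec(rbind(c(80, 30, 80, 130)), imageSize = c(160, 160))
  ph <- renderPhantom(sp, scale = 1.8)
  expect_equal(totalLength(ph$truth), 100 * 1.8)
  expect_equal(nBranchPoints(ph$truth), 0)
  expect_equal(totalArea(ph$truth), sum(ph$mask) * 1.8^2)

  # the same segment rotated 45 degrees about its centre: identical truth length
  d <- 50 / sqrt(2)
  rot <- phantomSpec(rbind(c(80 - d, 80 - d, 80 + d, 80 + d)),
                     imageSize = c(160, 160))
  expect_equal(totalLength(renderPhantom(rot)$truth),
               totalLength(renderPhantom(phantomSpec(
                 rbind(c(80, 30, 80, 130)), imageSize = c(160, 160)))$truth))

  # junction counting from segment geometry
  X <- rbind(c(20, 20, 120, 120), c(20, 120, 120, 20))
  expect_equal(nBranchPoints(renderPhantom(phantomSpec(X, imageSize = c(140, 140)))$truth), 1)
  Tj <- rbind(c(70, 10, 70, 130), c(70, 70, 130, 70))
  expect_equal(nBranchPoints(renderPhantom(phantomSpec(Tj, imageSize = c(140, 140)))$truth), 1)
  corner <- rbind(c(10, 10, 10, 100), c(10, 100, 100, 100))  # polyline corner
  expect_equal(nBranchPoints(renderPhantom(phantomSpec(corner, imageSize = c(140, 140)))$truth), 0)

  # blank control
  blank <- renderPhantom(phantomSpec(NULL, imageSize = c(64, 64)))
  expect_equal(totalLength(blank$truth), 0)
  expect_equal(totalArea(blank$truth), 0)
})

test_that("salt-and-pepper noise has binomial density and a reproducible seed", {
  img <- array(128, dim = c(100, 100, 3))

  expect_identical(addSaltPepper(img, 0), img)

  noisy <- addSaltPepper(img, 0.05, seed = 7L)
  flipped <- sum(noisy[, , 1] != 128)
  expect_gt(flipped, 500 - 70)   # binomial 3 sigma around n * p = 500
  expect_lt(flipped, 500 + 70)
  expect_true(all(noisy[, , 1] %in% c(0, 128, 255)))

  expect_identical(addSaltPepper(img, 0.05, seed = 7L), noisy)
  expect_false(identical(addSaltPepper(img, 0.05, seed = 8L), noisy))

  # the caller's RNG stream is untouched
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(addSaltPepper(img, 0.1, seed = 1L)); b <- runif(1)
  expect_identical(a, b)
})

test_that("the validation suite covers the archetypes with positive truth", {
  suite <- validationSuite(scale = 1, seed = 1)
  noiseless <- Filter(function(e) e$noise == 0, suite)
  expect_gte(length(noiseless), 20)
  expect_gte(length(suite) - length(noiseless), 1)

  for (e in noiseless) {
    if (e$name == "blank") {
      expect_equal(totalLength(e$truth), 0)
    } else {
      expect_gt(totalLength(e$truth), 0, label = e$name)
    }
  }
  # junction-bearing archetypes present
  nj <- vapply(suite, function(e) nBranchPoints(e$truth), numeric(1))
  expect_true(any(nj >= 4))   # grids
  expect_true(any(nj == 1))   # single junctions

  # rendering is deterministic, including the noisy variants
  s2 <- validationSuite(scale = 1, seed = 1)
  for (nm in names(suite))
    expect_identical(suite[[nm]]$image, s2[[nm]]$image, label = nm)
})

test_that("suite export writes TIFFs plus a ground-truth table that round-trips", {
  td <- withr::local_tempdir()
  csv <- writeValidationSuite(td, scale = 1, seed = 1)
  gt <- read.csv(csv)
  expect_true(all(file.exists(file.path(td, gt$file))))
  suite <- validationSuite(scale = 1, seed = 1)
  expect_identical(nrow(gt), length(suite))
  e <- suite$hline
  expect_identical(loadImage(file.path(td, "hline.tif")), e$image)
  expect_equal(gt$length_um[gt$file == "hline.tif"], totalLength(e$truth))
})

test_that("edge-based detection tolerates a linear illumination gradient", {
  ph <- renderPhantom(bar_phantom(len = 100, width = 5))
  img <- addIlluminationGradient(ph$image, 60)
  expect_true(all(img >= 0 & img <= 255))
  expect_true(all(img[, , 1] >= ph$image[, , 1]))   # ramp only adds intensity
  m <- tubemorph:::.analyze_array(img, phantomProfile())$metrics
  expect_lt(abs(totalLength(m) - 100) / 100, 0.03)
  expect_equal(nBranchPoints(m), 0)
})
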