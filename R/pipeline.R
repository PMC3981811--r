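.OVERLAY_COLORS <- list(
  edges    = c(0, 180, 0),
  skeleton = c(220, 0, 0),
  area     = c(0, 90, 220),
  nodes    = c(230, 200, 0)
)

#' Region of interest: the non-black part of an image
#'
#' For images with a black surround (e.g. retinal fundus photographs), the
#' analysis can be restricted to pixels whose channel-mean luminance exceeds
#' \code{threshold}; the region is then eroded by 3 px to avoid the strong
#' artificial gradient at the surround boundary.
#'
#' @param img numeric array \code{c(h, w, 3)}.
#' @param threshold luminance cut-off, default 10 (of 255).
#' @return logical matrix.
#' @export
nonblackRoi <- function(img, threshold = 10) {
  stopifnot(is.array(img), length(dim(img)) == 3)
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  .disc_erode(lum > threshold, 3)
}

# core analysis of an in-memory RGB array; shared by analyzeImage and tests
.analyze_array <- function(img, profile, roiMode = c("none", "nonblack"),
                           sourceFile = "") {
  roiMode <- match.arg(roiMode)
  gray <- toGrayscale(img)
  roi <- if (roiMode == "nonblack") nonblackRoi(img) else NULL
  edges <- detectTubes(gray, profile, roi = roi)
  skel <- clipSpurs(skeletonize(edges), profile@clip)
  metrics <- computeMetrics(edges, skel, profile, sourceFile = sourceFile)
  list(gray = gray, edges = edges, skeleton = skel, metrics = metrics,
       nodes = consolidateNodes(findBranchPixels(skel), profile@radius))
}

.write_overlays <- function(img, res, stem, dirs) {
  h <- nrow(res$edges@mask); w <- ncol(res$edges@mask)
  skel10 <- .disc_dilate(res$skeleton@mask, 10)
  nodemask <- matrix(FALSE, h, w)
  if (nrow(res$nodes) > 0) {
    ij <- cbind(pmin(pmax(round(res$nodes$row), 1), h),
                pmin(pmax(round(res$nodes$col), 1), w))
    nodemask[ij] <- TRUE
    nodemask <- .disc_dilate(nodemask, 10)
  }
  # the tube-area record shows the surviving area mask inverted
  lab <- .label_components(res$edges@mask, 8L)
  areamask <- res$edges@mask
  if (max(lab) > 0L) {
    hits <- tabulate(lab[res$skeleton@mask & lab > 0L], nbins = max(lab))
    areamask <- matrix(lab > 0L & hits[pmax(lab, 1L)] >= 1, h, w)
    areamask[lab == 0L] <- FALSE
  }
  masks <- list(edges = res$edges@mask, skeleton = skel10,
                area = !areamask, nodes = nodemask)
  written <- character(0)
  for (ty in names(masks)) {
    path <- file.path(dirs[[ty]], paste0(stem, "_", ty, ".tif"))
    writeOverlay(img, masks[[ty]], .OVERLAY_COLORS[[ty]], path)
    written <- c(written, path)
  }
  written
}

#' Analyze a single image
#'
#' The complete single-image ("sandbox") analysis: load, convert to
#' grayscale, detect tube-like structures, thin to a backbone, clip spurs
#' and compute the four tube metrics. When \code{saveImages} is on, four
#' record-of-analysis overlays are written next to the image (or under
#' \code{outDir}): detected edges, the backbone dilated by 10 px, the
#' inverted surviving-area mask and the consolidated nodes dilated by 10 px.
#' An image in which nothing is detected yields zero metrics, not an error.
#'
#' @param path path to a TIFF image.
#' @param profile a [ParameterProfile-class].
#' @param saveImages write the overlay TIFF set.
#' @param roiMode \code{"none"} or \code{"nonblack"} (restrict detection to
#'   the non-black region, see [nonblackRoi()]).
#' @param outDir directory for overlays (default: the image's directory).
#' @return an [AnalysisRecord-class].
#' @export
analyzeImage <- function(path, profile, saveImages = FALSE,
                         roiMode = c("none", "nonblack"), outDir = NULL) {
  roiMode <- match.arg(roiMode)
  stopifnot(is(profile, "ParameterProfile"))
  validObject(profile)
  img <- loadImage(path)
  res <- .analyze_array(img, profile, roiMode, sourceFile = basename(path))
  written <- character(0)
  if (saveImages) {
    base <- if (is.null(outDir)) dirname(path) else outDir
    dir.create(base, showWarnings = FALSE, recursive = TRUE)
    stem <- sub("\\.[^.]*$", "", basename(path))
    dirs <- as.list(rep(base, 4)); names(dirs) <- names(.OVERLAY_COLORS)
    written <- .write_overlays(img, res, stem, dirs)
  }
  new("AnalysisRecord", sourceFile = basename(path), metrics = res$metrics,
      profile = profile, outputsWritten = written, error = "")
}

#' Batch analysis of an image set
#'
#' Runs [analyzeImage()] over a list of files with a single parameter
#' profile -- the profile is the only input required; no per-image
#' interaction happens. A CSV report with one row per file (\code{file,
#' length_um, area_um2, n_nodes, thickness_um, error}) is written to
#' \code{outDir}. A failing image is logged in its row's \code{error} column
#' and the batch continues. With \code{saveImages}, the four overlay types
#' go to per-type subdirectories of \code{outDir}. Per-file results are
#' independent, so rerunning with the same profile reproduces the metric
#' columns exactly.
#'
#' @param files character vector of image paths (>= 1).
#' @param profile a [ParameterProfile-class].
#' @param outDir output directory (created if needed).
#' @param saveImages write overlay sets.
#' @param roiMode passed to [analyzeImage()].
#' @param reportName file name of the CSV report.
#' @return path of the CSV report; the list of [AnalysisRecord-class]
#'   objects is attached as attribute \code{"records"}.
#' @export
runBatch <- function(files, profile, outDir, saveImages = FALSE,
                     roiMode = c("none", "nonblack"),
                     reportName = "report.csv") {
  stopifnot(length(files) >= 1, is(profile, "ParameterProfile"))
  roiMode <- match.arg(roiMode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dirs <- NULL
  if (saveImages) {
    dirs <- lapply(names(.OVERLAY_COLORS), function(ty) {
      d <- file.path(outDir, ty)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      d
    })
    names(dirs) <- names(.OVERLAY_COLORS)
  }
  records <- vector("list", length(files))
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      img <- loadImage(f)
      res <- .analyze_array(img, profile, roiMode, sourceFile = basename(f))
      written <- if (saveImages)
        .write_overlays(img, res, sub("\\.[^.]*$", "", basename(f)), dirs)
      else character(0)
      new("AnalysisRecord", sourceFile = basename(f), metrics = res$metrics,
          profile = profile, outputsWritten = written, error = "")
    }, tubemorph_error = function(e) {
      new("AnalysisRecord", sourceFile = basename(f),
          metrics = new("TubeMetrics", totalLength = 0, totalArea = 0,
                        nBranchPoints = 0, avgThickness = 0, sourceFile = basename(f)),
          profile = profile, outputsWritten = character(0),
          error = conditionMessage(e))
    })
    m <- rec@metrics
    message(sprintf(
      "tubemorph: file=%s length_um=%.4f area_um2=%.4f n_nodes=%d thickness_um=%s error=%s wall_s=%.2f",
      basename(f), m@totalLength, m@totalArea, as.integer(m@nBranchPoints),
      ifelse(is.na(m@avgThickness), "NA", sprintf("%.4f", m@avgThickness)),
      ifelse(nzchar(rec@error), shQuote(rec@error), "none"),
      proc.time()[["elapsed"]] - t0))
    records[[i]] <- rec
    rows[[i]] <- data.frame(
      file = basename(f),
      length_um = if (nzchar(rec@error)) NA_real_ else m@totalLength,
      area_um2 = if (nzchar(rec@error)) NA_real_ else m@totalArea,
      n_nodes = if (nzchar(rec@error)) NA_integer_ else as.integer(m@nBranchPoints),
      thickness_um = if (nzchar(rec@error)) NA_real_ else m@avgThickness,
      error = rec@error,
      stringsAsFactors = FALSE)
  }
  report <- file.path(outDir, reportName)
  utils::write.csv(do.call(rbind, rows), report, row.names = FALSE)
  structure(report, records = records)
}
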