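#' Total tube length from a skeleton
#'
#' Sums the length contribution of every distinct pair of 8-adjacent
#' backbone pixels: an orthogonal (horizontal/vertical) adjacency counts as
#' one pixel length, a diagonal adjacency as 1.414 pixel lengths. Each
#' adjacency is counted exactly once, and a diagonal pair that is already
#' joined through a shared orthogonal neighbour is skipped (the standard
#' redundant-diagonal correction, so an L-corner is not double-counted). The
#' pixel total is converted to microns with \code{scale}.
#'
#' @param skel a [SkeletonMask-class] or logical matrix.
#' @param scale microns per pixel (> 0).
#' @return total length in microns (0 for an empty skeleton).
#' @examples
#' m <- matrix(FALSE, 3, 12); m[2, 1:11] <- TRUE
#' measureLength(m, 1)             # 11-px line -> 10
#' d <- diag(11) > 0
#' measureLength(d, 1)             # diagonal   -> 14.14
#' @export
measureLength <- function(skel, scale = 1) {
  stopifnot(scale > 0)
  m <- .as_mask(skel)
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m) || nr < 1 || nc < 1) return(0)
  horiz <- if (nc > 1) sum(m[, -nc] & m[, -1]) else 0
  vert  <- if (nr > 1) sum(m[-nr, ] & m[-1, ]) else 0
  diag_main <- 0; diag_anti <- 0
  if (nr > 1 && nc > 1) {
    a  <- m[-nr, -nc]; b  <- m[-1, -1]    # (i,j) with (i+1,j+1)
    s1 <- m[-1, -nc];  s2 <- m[-nr, -1]   # shared orthogonal neighbours
    diag_main <- sum(a & b & !s1 & !s2)
    diag_anti <- sum(s1 & s2 & !a & !b)   # (i+1,j) with (i,j+1)
  }
  (horiz + vert + 1.414 * (diag_main + diag_anti)) * scale
}

#' Raw branch-point pixels of a skeleton
#'
#' Flags every backbone pixel connected to three or more backbone pixels.
#' Thinning often yields several such pixels at one physical junction; use
#' [consolidateNodes()] to merge them.
#'
#' @param skel a [SkeletonMask-class] or logical matrix.
#' @return logical matrix marking raw branch pixels.
#' @export
findBranchPixels <- function(skel) {
  m <- .as_mask(skel)
  m & (.neighbour_counts(m) >= 3L)
}

#' Consolidate raw branch pixels into branch points
#'
#' Groups raw branch pixels by single-linkage clustering at Euclidean
#' distance <= \code{radius} (two pixels belong to one node when a chain of
#' pixels at most \code{radius} apart links them) and replaces each group by
#' its coordinate mean. Deterministic: pixels are seeded in raster order and
#' the result is sorted by (row, col).
#'
#' @param nodes logical matrix of raw branch pixels, see
#'   [findBranchPixels()].
#' @param radius consolidation radius in pixels (>= 0).
#' @return data frame with columns \code{row}, \code{col} (mean coordinates)
#'   and \code{support} (raw pixels merged); zero rows for an empty input.
#' @examples
#' m <- matrix(FALSE, 5, 10); m[1, c(1, 5)] <- TRUE
#' consolidateNodes(m, 30)    # one node at column 3
#' @export
consolidateNodes <- function(nodes, radius) {
  stopifnot(radius >= 0)
  m <- .as_mask(nodes)
  idx <- which(m, arr.ind = TRUE)
  empty <- data.frame(row = numeric(0), col = numeric(0), support = integer(0))
  if (nrow(idx) == 0) return(empty)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  if (n == 1) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(idx), method = "single")
    cl <- stats::cutree(hc, h = radius)
  }
  out <- do.call(rbind, lapply(split(seq_len(n), cl), function(i) {
    data.frame(row = mean(idx[i, 1]), col = mean(idx[i, 2]),
               support = length(i))
  }))
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total tube area gated by skeleton contribution
#'
#' An object detected as tube-like is included in the area only when it
#' contributes to the total length: each connected component of the edge
#' mask is kept when its intersection with the backbone contains at least
#' \code{overlap} pixels. The surviving foreground pixel count is converted
#' to square microns with \code{scale^2}.
#'
#' @param edges an [EdgeMask-class] or logical matrix.
#' @param skel a [SkeletonMask-class] or logical matrix of equal size.
#' @param overlap minimum skeleton pixels per component (>= 0).
#' @param scale microns per pixel.
#' @return total area in square microns.
#' @export
measureArea <- function(edges, skel, overlap, scale = 1) {
  stopifnot(overlap >= 0, scale > 0)
  e <- .as_mask(edges); s <- .as_mask(skel)
  if (!all(dim(e) == dim(s)))
    .tm_error("edge and skeleton masks differ in size", "tubemorph_dim_mismatch")
  lab <- .label_components(e, 8L)
  if (max(lab) == 0L) return(0)
  hits <- tabulate(lab[s & lab > 0L], nbins = max(lab))
  areas <- .component_areas(lab)
  sum(areas[hits >= overlap]) * scale^2
}

#' Average tube thickness
#'
#' Total area divided by total length. Both zero gives 0 (empty image);
#' zero length with positive area is undefined and reported as \code{NA}.
#'
#' @param totalArea total tube area, square microns.
#' @param totalLength total tube length, microns.
#' @return thickness in microns, or \code{NA}.
#' @export
averageThickness <- function(totalArea, totalLength) {
  stopifnot(totalArea >= 0, totalLength >= 0)
  if (totalLength == 0) {
    if (totalArea == 0) return(0)
    return(NA_real_)
  }
  totalArea / totalLength
}

#' Relative percent difference between two measurements
#'
#' The inter-operator discrepancy statistic: absolute difference divided by
#' the smaller of the two values, times 100. Symmetric in its arguments;
#' undefined (\code{NA}) when both are zero.
#'
#' @param l1,l2 non-negative measurements (e.g. total lengths in microns).
#' @return percent difference.
#' @examples
#' relativePercentDifference(150, 100)   # 50
#' @export
relativePercentDifference <- function(l1, l2) {
  stopifnot(l1 >= 0, l2 >= 0)
  if (l1 == 0 && l2 == 0) return(NA_real_)
  abs(l1 - l2) / min(l1, l2) * 100
}

#' Compute all tube metrics from a mask/backbone pair
#'
#' Bundles [measureLength()], [measureArea()], [findBranchPixels()] +
#' [consolidateNodes()] and [averageThickness()] into a
#' [TubeMetrics-class]. Branch points are counted on the (already clipped)
#' backbone passed in.
#'
#' @param edges an [EdgeMask-class].
#' @param skel the clipped [SkeletonMask-class] derived from it.
#' @param profile a [ParameterProfile-class].
#' @param sourceFile file name recorded in the result.
#' @return a [TubeMetrics-class].
#' @export
computeMetrics <- function(edges, skel, profile, sourceFile = "") {
  stopifnot(is(profile, "ParameterProfile"))
  len <- measureLength(skel, profile@scale)
  area <- measureArea(edges, skel, profile@overlap, profile@scale)
  nodes <- consolidateNodes(findBranchPixels(skel), profile@radius)
  new("TubeMetrics",
      totalLength = len, totalArea = area,
      nBranchPoints = as.numeric(nrow(nodes)),
      avgThickness = averageThickness(area, len),
      sourceFile = sourceFile)
}
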