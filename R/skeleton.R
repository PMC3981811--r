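#' Reduce a tube mask to a one-pixel-wide backbone
#'
#' Iteratively erodes object border pixels, never removing a pixel whose
#' deletion would split an object, merge two objects, or open/close a hole
#' (the Euler characteristic is preserved), until the mask stops changing.
#' Pixels with a single neighbour (line ends) are kept, so tube tips are not
#' shortened. Border pixels are scanned in alternating directional
#' sub-iterations (N, S, E, W) to avoid directional bias. The fixed point is
#' idempotent: skeletonizing a skeleton returns it unchanged.
#'
#' @param edges an [EdgeMask-class] or logical matrix.
#' @return a [SkeletonMask-class] with exactly as many connected components
#'   as the input.
#' @examples
#' m <- matrix(FALSE, 9, 15); m[4:6, 3:13] <- TRUE
#' sum(maskMatrix(skeletonize(m)))   # a thin path remains
#' @export
skeletonize <- function(edges) {
  m <- .as_mask(edges)
  new("SkeletonMask", mask = .thin_mask(m))
}

#' Clip skeleton spurs
#'
#' From every skeleton endpoint (a pixel with exactly one neighbour), walks
#' inward removing up to \code{clip} pixels, stopping early when the next
#' pixel is a branch point (three or more neighbours). This removes the
#' short endpoint chains thinning introduces and excludes small tube-like
#' fragments from quantification. With \code{clip = Inf} the pass repeats
#' until nothing changes, which eliminates branch-free objects entirely
#' (junction cores survive). \code{clip = 0} is the identity.
#'
#' @param skel a [SkeletonMask-class] or logical matrix.
#' @param clip pixels to trim from each endpoint, or \code{Inf}.
#' @return a [SkeletonMask-class].
#' @examples
#' path <- matrix(FALSE, 5, 30); path[3, 5:24] <- TRUE   # 20-px path
#' sum(maskMatrix(clipSpurs(path, 5)))                    # 10 px remain
#' sum(maskMatrix(clipSpurs(path, Inf)))                  # annihilated
#' @export
clipSpurs <- function(skel, clip) {
  stopifnot(length(clip) == 1, !is.na(clip), clip >= 0)
  m <- .as_mask(skel)
  if (clip == 0) return(new("SkeletonMask", mask = m))
  new("SkeletonMask", mask = .clip_spurs(m, as.numeric(clip)))
}
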