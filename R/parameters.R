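.PROFILE_KEYS <- c("scale", "cannyConnect", "dilate", "fill", "clean",
                   "clip", "overlap", "radius")
.PROFILE_VERSION <- 1L

#' Create a parameter profile
#'
#' Constructs and validates a [ParameterProfile-class]. Defaults are the
#' midpoints of the typical working ranges (the upper ends of the open-ended
#' \code{fill}/\code{clean} ranges taken as 5000 and 10000): they are a
#' starting point for interactive tuning on a representative image, not
#' universal constants.
#'
#' @param scale microns per pixel (> 0).
#' @param cannyConnect,dilate closing radii in pixels.
#' @param fill,clean area thresholds in pixels (strictly-smaller-than).
#' @param clip spur-clipping budget in pixels, or \code{Inf}.
#' @param overlap minimum skeleton pixels per object for area inclusion.
#' @param radius node consolidation radius in pixels.
#' @return a validated [ParameterProfile-class].
#' @examples
#' parameterProfile(scale = 1.8, cannyConnect = 8, clip = Inf)
#' @export
parameterProfile <- function(scale = 2.75, cannyConnect = 7, dilate = 4,
                             fill = 2600, clean = 5500, clip = 50,
                             overlap = 10, radius = 90) {
  new("ParameterProfile",
      scale = as.numeric(scale), cannyConnect = as.numeric(cannyConnect),
      dilate = as.numeric(dilate), fill = as.numeric(fill),
      clean = as.numeric(clean), clip = as.numeric(clip),
      overlap = as.numeric(overlap), radius = as.numeric(radius))
}

#' Parameter profile tuned for the in-silico validation suite
#'
#' The profile under which the pipeline recovers the analytic ground truth of
#' every noiseless [validationSuite()] phantom to within 1%, obtained the same
#' way a profile is tuned for a real study: adjusted on representative images
#' until each feature was recovered. Relative to the bright-field defaults,
#' the area thresholds are small (phantom strokes are thin and clean), spur
#' clipping is off (phantom tubes carry no debris and clipping shortens every
#' open tube end by \code{clip} pixels), and the consolidation radius is at
#' the low end of its range (phantom junctions are compact).
#'
#' @param scale microns per pixel of the rendered phantoms.
#' @return a [ParameterProfile-class].
#' @export
phantomProfile <- function(scale = 1) {
  parameterProfile(scale = scale, cannyConnect = 4, dilate = 2, fill = 500,
                   clean = 300, clip = 0, overlap = 10, radius = 30)
}

#' Save a parameter profile to disk
#'
#' Writes a human-readable flat JSON file holding the eight parameters plus a
#' \code{version} key. An infinite \code{clip} is serialized as the literal
#' token \code{"Inf"}.
#'
#' @param profile a [ParameterProfile-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [loadProfile()]
#' @export
saveProfile <- function(profile, path) {
  stopifnot(is(profile, "ParameterProfile"))
  validObject(profile)
  vals <- lapply(.PROFILE_KEYS, function(k) {
    v <- slot(profile, k)
    if (is.infinite(v)) "Inf" else v
  })
  names(vals) <- .PROFILE_KEYS
  vals$version <- .PROFILE_VERSION
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load and validate a parameter profile
#'
#' Reads a JSON profile written by [saveProfile()]. All eight parameter keys
#' must be present; out-of-domain values are rejected with an error naming
#' the offending key, and unknown extra keys produce a warning, not a
#' failure. The token \code{"Inf"} is parsed back to an infinite \code{clip}.
#'
#' @param path path to a profile JSON file.
#' @return a validated [ParameterProfile-class].
#' @export
loadProfile <- function(path) {
  if (!file.exists(path))
    .tm_error(paste0("profile file not found: ", path), "tubemorph_not_found")
  vals <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e)
                     .tm_error(paste0("profile file does not parse as JSON: ", path),
                               "tubemorph_bad_format"))
  missing <- setdiff(.PROFILE_KEYS, names(vals))
  if (length(missing))
    .tm_error(paste0("profile is missing required key(s): ",
                     paste(missing, collapse = ", ")), "tubemorph_bad_profile")
  extra <- setdiff(names(vals), c(.PROFILE_KEYS, "version"))
  if (length(extra))
    warning("ignoring unknown profile key(s): ", paste(extra, collapse = ", "))
  num <- function(k) {
    v <- vals[[k]]
    if (is.character(v) && toupper(v) %in% c("INF", "INFINITY")) return(Inf)
    suppressWarnings(as.numeric(v))
  }
  args <- lapply(.PROFILE_KEYS, num)
  names(args) <- .PROFILE_KEYS
  bad <- names(args)[vapply(args, function(v) length(v) != 1 || is.na(v), logical(1))]
  if (length(bad))
    .tm_error(paste0("profile key(s) not numeric: ", paste(bad, collapse = ", ")),
              "tubemorph_bad_profile")
  p <- tryCatch(do.call(parameterProfile, args), error = function(e)
    .tm_error(paste0("invalid profile: ", conditionMessage(e)), "tubemorph_bad_profile"))
  p
}
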