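#' Microscope calibration
#'
#' Bundles the pixel-size calibration of a confocal image with a free-text
#' objective label. All geometric conversions in the package (areas in mm²,
#' equivalent particle diameters in µm, cross-correlation shifts in µm) go
#' through a `calibration` object.
#'
#' Typical values for the imaging setups this pipeline targets are
#' 0.124 µm/px (x100 NA 1.4 oil), 0.132 µm/px (x63 NA 1.4 oil) and
#' 0.311 µm/px (x40 NA 1.0) on 1024 x 1024 frames.
#'
#' @param pixel_size Side length of one pixel in micrometres. Must be > 0.
#' @param objective Free-text objective label (e.g. `"x100 NA 1.4 oil"`).
#' @return An object of class `calibration`: a list with elements
#'   `pixel_size` and `objective`.
#' @examples
#' cal <- calibration(0.124, "x100 NA 1.4 oil")
#' image_area_mm2(cal, 1024, 1024)
#' @export
calibration <- function(pixel_size, objective = "") {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, is.finite(pixel_size))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(pixel_size = as.numeric(pixel_size),
                 objective = as.character(objective)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.4g um/px%s\n", x$pixel_size,
              if (nzchar(x$objective)) paste0(" (", x$objective, ")") else ""))
  invisible(x)
}

as_pixel_size <- function(calibration) {
  if (inherits(calibration, "calibration")) return(calibration$pixel_size)
  if (is.numeric(calibration) && length(calibration) == 1L && calibration > 0)
    return(as.numeric(calibration))
  stop("supply a calibration() object or a positive pixel size in um")
}

#' Image area in square millimetres
#'
#' Computes `width * height * pixel_size^2 * 1e-6`, the field-of-view area of
#' a raster in mm². The value is returned at full precision; round to three
#' significant figures for display (e.g. a 1024 x 1024 frame at 0.124 µm/px
#' is 0.0161 mm², and at 0.311 µm/px is 0.101 mm²).
#'
#' @param calibration A [calibration()] object (or bare pixel size in µm).
#' @param width,height Raster dimensions in pixels (>= 1).
#' @return Area in mm² (numeric scalar, full precision).
#' @examples
#' signif(image_area_mm2(calibration(0.124), 1024, 1024), 3) # 0.0161
#' @export
image_area_mm2 <- function(calibration, width, height) {
  p <- as_pixel_size(calibration)
  stopifnot(is.numeric(width), is.numeric(height))
  if (width < 1 || height < 1) stop("width and height must be >= 1 pixel")
  width * height * p^2 * 1e-6
}

#' Equivalent circular diameter of a particle
#'
#' Converts a pixel count into the diameter (µm) of the circle with the same
#' area: `d = 2 * sqrt(n * pixel_size^2 / pi)`. At 0.124 µm/px the size-class
#' boundaries of 10 and 100 pixels correspond to roughly 0.4 µm and 1.4 µm.
#'
#' @param n_pixels Number of pixels in the particle (>= 1); vectorised.
#' @inheritParams image_area_mm2
#' @return Diameter(s) in micrometres, full precision.
#' @examples
#' round(equivalent_diameter(100, calibration(0.124)), 1) # 1.4
#' @export
equivalent_diameter <- function(n_pixels, calibration) {
  p <- as_pixel_size(calibration)
  if (any(n_pixels < 1)) stop("n_pixels must be >= 1")
  2 * sqrt(n_pixels * p^2 / pi)
}

size_class_levels <- function(subdivide_large = FALSE) {
  if (subdivide_large) c("small", "medium", "large_101_200", "large_gt200")
  else c("small", "medium", "large")
}

#' Particle size class from pixel count
#'
#' Assigns each particle to one of three size groups by pixel count:
#' small (1-10 px), medium (11-100 px), large (> 100 px). When
#' `subdivide_large = TRUE` (used by the permeabilization/compartment
#' analysis) the large group is split at 200 px into `large_101_200` and
#' `large_gt200`. Bins are disjoint and exhaustive for all counts >= 1.
#'
#' @param n_pixels Integer pixel counts (>= 1); vectorised.
#' @param subdivide_large Split the large class at 200 px?
#' @return A factor with levels `small`, `medium`, `large` (or the
#'   four-level subdivision).
#' @examples
#' size_class(c(10, 11, 100, 101, 201))
#' @export
size_class <- function(n_pixels, subdivide_large = FALSE) {
  if (any(n_pixels < 1)) stop("n_pixels must be >= 1")
  breaks <- if (subdivide_large) c(0, 10, 100, 200, Inf) else c(0, 10, 100, Inf)
  cut(n_pixels, breaks = breaks, labels = size_class_levels(subdivide_large))
}

#' Convert a pixel distance to micrometres
#'
#' Multiplies a (possibly fractional) pixel distance — e.g. a mean
#' cross-correlation peak shift — by the pixel size.
#'
#' @param px Distance in pixels; vectorised.
#' @inheritParams image_area_mm2
#' @return Distance in micrometres.
#' @examples
#' round(px_to_um(5.3, calibration(0.124)), 2) # 0.66
#' @export
px_to_um <- function(px, calibration) px * as_pixel_size(calibration)

#' Express one measurement as a percentage of another
#'
#' Convenience helper used when relating area densities of two channels,
#' e.g. a tight-junction marker expressed as percent of the adherens-junction
#' reference in the same region.
#'
#' @param a,b Numeric vectors (numerator and denominator).
#' @return `100 * a / b`, unrounded.
#' @examples
#' round(percent_of(7.0, 27.1)) # 26
#' @export
percent_of <- function(a, b) 100 * a / b
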