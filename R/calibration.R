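#' Spatial calibration: pixel-to-micron scaling
#'
#' A calibration ties image pixels to physical distance. It can be built
#' directly from a known scale (micrometres per pixel) or derived from the
#' camera pixel pitch and the objective magnification, in which case
#' \code{scale = camera_pixel_um / magnification}. Typical pressure-myography
#' rigs pair a 3.45 um-pixel CMOS camera with a 4x or 10x objective
#' (0.8625 and 0.345 um/px sampling respectively).
#'
#' @param camera_pixel_um Physical pixel pitch of the camera sensor, in
#'   micrometres. Must be positive.
#' @param magnification Total optical magnification (dimensionless). Must be
#'   positive.
#' @param label Optional name for the calibration (e.g. \code{"10x CMOS"}),
#'   used when calibrations are stored in a session config.
#' @return An object of class \code{calibration} with fields \code{scale}
#'   (um per pixel), \code{camera_pixel_um}, \code{magnification} and
#'   \code{label}.
#' @examples
#' cal <- make_calibration(3.45, 10)
#' cal$scale            # 0.345 um/px
#' px_to_um(cal, 580)   # 200.1 um
#' @seealso [px_to_um()], [calibration()]
#' @export
make_calibration <- function(camera_pixel_um, magnification, label = "") {
  if (!is.numeric(camera_pixel_um) || length(camera_pixel_um) != 1L ||
      !is.finite(camera_pixel_um) || camera_pixel_um <= 0) {
    stop("invalid calibration: `camera_pixel_um` must be a positive number")
  }
  if (!is.numeric(magnification) || length(magnification) != 1L ||
      !is.finite(magnification) || magnification <= 0) {
    stop("invalid calibration: `magnification` must be a positive number")
  }
  calibration(scale = camera_pixel_um / magnification,
              camera_pixel_um = camera_pixel_um,
              magnification = magnification,
              label = label)
}

#' Construct a calibration from a direct um-per-pixel scale
#'
#' @param scale Micrometres per pixel; must be positive.
#' @param camera_pixel_um,magnification Optional provenance. When both are
#'   given they must be consistent with \code{scale} to within 1e-9.
#' @param label Optional name.
#' @return A \code{calibration} object.
#' @export
calibration <- function(scale, camera_pixel_um = NULL, magnification = NULL,
                        label = "") {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("invalid calibration: `scale` must be a positive number")
  }
  if (!is.null(camera_pixel_um) && !is.null(magnification)) {
    if (abs(scale - camera_pixel_um / magnification) > 1e-9) {
      stop("invalid calibration: `scale` inconsistent with ",
           "`camera_pixel_um` / `magnification`")
    }
  }
  structure(list(scale = scale,
                 camera_pixel_um = camera_pixel_um,
                 magnification = magnification,
                 label = label),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration%s> %.6g um/px",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$scale))
  if (!is.null(x$camera_pixel_um) && !is.null(x$magnification)) {
    cat(sprintf(" (%.4g um pixels at %.4gx)",
                x$camera_pixel_um, x$magnification))
  }
  cat("\n")
  invisible(x)
}

#' Convert a pixel length to micrometres
#'
#' Linear conversion \code{length_px * cal$scale}. Vectorised over
#' \code{length_px}.
#'
#' @param cal A [calibration()] object.
#' @param length_px Length(s) in pixels; must be non-negative.
#' @return Length(s) in micrometres.
#' @export
px_to_um <- function(cal, length_px) {
  stopifnot(inherits(cal, "calibration"))
  if (any(!is.finite(length_px)) || any(length_px < 0)) {
    stop("`length_px` must be non-negative")
  }
  length_px * cal$scale
}

#' Convert a micrometre length to pixels
#'
#' Inverse of [px_to_um()].
#' @inheritParams px_to_um
#' @param length_um Length(s) in micrometres; non-negative.
#' @return Length(s) in pixels.
#' @export
um_to_px <- function(cal, length_um) {
  stopifnot(inherits(cal, "calibration"))
  if (any(!is.finite(length_um)) || any(length_um < 0)) {
    stop("`length_um` must be non-negative")
  }
  length_um / cal$scale
}
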