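#' Define a measurement track line
#'
#' A track line is the locus along which intensity profiles are sampled and
#' vessel edges detected. Three kinds are supported, mirroring common
#' myograph workflows:
#' \describe{
#'   \item{\code{roi_horizontal}}{a rectangular region of interest scanned by
#'     \code{n_scanlines} evenly spaced horizontal rows;}
#'   \item{\code{roi_vertical}}{the same with vertical columns;}
#'   \item{\code{segment}}{a custom line drawn at any angle between two
#'     endpoints, with \code{2 * half_width + 1} parallel offset lines
#'     averaged into a single profile.}
#' }
#'
#' Coordinates are continuous, 0-based, with \code{x} the column and \code{y}
#' the row, and integer positions at pixel centres. Geometry is validated
#' against frame bounds when a frame is measured, not at construction, so a
#' line can be defined before its stack is loaded.
#'
#' @param id Small integer identifier (1-5). At most five lines may be
#'   tracked in one session.
#' @param kind One of \code{"roi_horizontal"}, \code{"roi_vertical"},
#'   \code{"segment"}.
#' @param x,y,width,height ROI rectangle (required for ROI kinds): corner at
#'   \code{(x, y)}, spanning \code{width} columns and \code{height} rows.
#' @param x0,y0,x1,y1 Segment endpoints (required for \code{"segment"}).
#'   Segment length must be at least 8 px.
#' @param n_scanlines Number of scanlines for ROI kinds (default 10).
#' @param half_width Perpendicular averaging half-width in px for segments
#'   (default 2, i.e. 5 parallel lines).
#' @param mode Imaging modality driving edge-detector dispatch: one of
#'   \code{"brightfield"}, \code{"fluorescence"}, \code{"ultrasound"},
#'   \code{"en_face"}.
#' @return An object of class \code{track_line}.
#' @examples
#' track_line(1, "roi_horizontal", x = 10, y = 20, width = 200, height = 60)
#' track_line(2, "segment", x0 = 5, y0 = 5, x1 = 105, y1 = 85,
#'            mode = "fluorescence")
#' @export
track_line <- function(id, kind = c("roi_horizontal", "roi_vertical", "segment"),
                       x = NULL, y = NULL, width = NULL, height = NULL,
                       x0 = NULL, y0 = NULL, x1 = NULL, y1 = NULL,
                       n_scanlines = 10L, half_width = 2,
                       mode = c("brightfield", "fluorescence", "ultrasound",
                                "en_face")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  id <- as.integer(id)
  stopifnot(length(id) == 1L, is.finite(id), id >= 1L)
  n_scanlines <- as.integer(n_scanlines)
  if (n_scanlines < 1L) stop("`n_scanlines` must be >= 1")
  if (!is.numeric(half_width) || half_width < 0) {
    stop("`half_width` must be >= 0")
  }
  if (kind == "segment") {
    if (is.null(x0) || is.null(y0) || is.null(x1) || is.null(y1)) {
      stop("segment lines need endpoints `x0`, `y0`, `x1`, `y1`")
    }
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    if (len < 8) stop("segment length must be >= 8 px (got ", signif(len, 4), ")")
    geometry <- list(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  } else {
    if (is.null(x) || is.null(y) || is.null(width) || is.null(height)) {
      stop("ROI lines need `x`, `y`, `width`, `height`")
    }
    if (width < 1 || height < 1) stop("ROI `width` and `height` must be >= 1")
    span <- if (kind == "roi_horizontal") width else height
    if (span < 8) stop("ROI scan span must be >= 8 px")
    geometry <- list(x = x, y = y, width = width, height = height)
  }
  structure(list(id = id, kind = kind, geometry = geometry,
                 n_scanlines = n_scanlines, half_width = half_width,
                 mode = mode),
            class = "track_line")
}

#' @export
print.track_line <- function(x, ...) {
  g <- x$geometry
  geom <- if (x$kind == "segment") {
    sprintf("(%g,%g)-(%g,%g), half_width %g", g$x0, g$y0, g$x1, g$y1,
            x$half_width)
  } else {
    sprintf("[%g,%g %gx%g], %d scanlines", g$x, g$y, g$width, g$height,
            x$n_scanlines)
  }
  cat(sprintf("<track_line %d> %s %s, mode %s\n", x$id, x$kind, geom, x$mode))
  invisible(x)
}

# Start point, unit direction and length (px) of one scanline of a track
# line. `scan_offset` indexes the scanline for ROI kinds (1..n_scanlines) or
# is a signed perpendicular shift in [-half_width, half_width] for segments.
scanline_geometry <- function(line, scan_offset) {
  g <- line$geometry
  if (line$kind == "roi_horizontal") {
    rows <- seq(g$y, g$y + g$height - 1, length.out = line$n_scanlines)
    k <- as.integer(scan_offset)
    if (k < 1L || k > line$n_scanlines) stop("scanline index out of range")
    list(x0 = g$x, y0 = rows[k], dx = 1, dy = 0, length = g$width - 1)
  } else if (line$kind == "roi_vertical") {
    cols <- seq(g$x, g$x + g$width - 1, length.out = line$n_scanlines)
    k <- as.integer(scan_offset)
    if (k < 1L || k > line$n_scanlines) stop("scanline index out of range")
    list(x0 = cols[k], y0 = g$y, dx = 0, dy = 1, length = g$height - 1)
  } else {
    if (abs(scan_offset) > line$half_width + 1e-12) {
      stop("segment `scan_offset` must lie in [-half_width, half_width]")
    }
    len <- sqrt((g$x1 - g$x0)^2 + (g$y1 - g$y0)^2)
    ux <- (g$x1 - g$x0) / len
    uy <- (g$y1 - g$y0) / len
    # perpendicular (rotate direction by +90 degrees)
    list(x0 = g$x0 - uy * scan_offset, y0 = g$y0 + ux * scan_offset,
         dx = ux, dy = uy, length = len)
  }
}

# Offsets enumerating every profile a line contributes to one measurement.
scan_offsets <- function(line) {
  if (line$kind == "segment") {
    h <- floor(line$half_width)
    seq(-h, h)
  } else {
    seq_len(line$n_scanlines)
  }
}

#' Bundle image frames into a stack
#'
#' @param frames A list of numeric matrices (grayscale intensity, arbitrary
#'   units), all with identical dimensions, in temporal order.
#' @param frame_interval Seconds between consecutive frames; positive.
#' @param calibration A [calibration()] object.
#' @param source_path Optional provenance string (e.g. the TIFF path).
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(frames, frame_interval, calibration,
                        source_path = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            inherits(calibration, "calibration"))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a positive number of seconds")
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) stop("frames must be numeric matrices")
    dim(f)
  }, integer(2))
  if (length(frames) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    stop("all frames must share identical dimensions")
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 calibration = calibration, source_path = source_path),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px, dt = %g s, %.4g um/px\n",
              length(x$frames), d[2], d[1], x$frame_interval,
              x$calibration$scale))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)
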