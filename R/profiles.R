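#' Sample an intensity profile along a track line
#'
#' Samples the frame at unit (1 px) steps along one scanline of a track line
#' by bilinear interpolation, producing the intensity function F whose
#' derivative dF/dx drives edge detection. On axis-aligned lines with integer
#' coordinates the samples equal direct row/column indexing exactly.
#'
#' @param frame Numeric matrix of intensities (rows = y, columns = x).
#' @param line A [track_line()].
#' @param scan_offset For ROI kinds, the scanline index in
#'   \code{1:n_scanlines}; for segments, a signed perpendicular shift in
#'   \code{[-half_width, half_width]} px.
#' @return An object of class \code{intensity_profile}: a list with
#'   \code{values} (samples at unit spacing), \code{origin} (continuous
#'   0-based \code{(x, y)} of the first sample) and \code{direction} (unit
#'   vector along the line).
#' @export
extract_profile <- function(frame, line, scan_offset = 1L) {
  stopifnot(is.matrix(frame), is.numeric(frame), inherits(line, "track_line"))
  sl <- scanline_geometry(line, scan_offset)
  n <- floor(sl$length) + 1L
  if (n < 8L) stop("profile would have fewer than 8 samples")
  t <- seq(0, n - 1L)
  xs <- sl$x0 + sl$dx * t
  ys <- sl$y0 + sl$dy * t
  vals <- bilinear_sample(frame, xs, ys)
  intensity_profile(vals, origin = c(sl$x0, sl$y0),
                    direction = c(sl$dx, sl$dy))
}

#' @rdname extract_profile
#' @param values Numeric vector of at least 8 intensity samples at unit
#'   spacing.
#' @param origin,direction Placement of the profile in frame coordinates.
#' @export
intensity_profile <- function(values, origin = c(0, 0), direction = c(1, 0)) {
  values <- as.numeric(values)
  if (length(values) < 8L) stop("an intensity profile needs >= 8 samples")
  structure(list(values = values, origin = origin, direction = direction),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %d samples from (%.2f, %.2f) along (%.3f, %.3f)\n",
              length(x$values), x$origin[1], x$origin[2],
              x$direction[1], x$direction[2]))
  invisible(x)
}

#' @export
length.intensity_profile <- function(x) length(x$values)

# Bilinear interpolation at continuous 0-based (x, y); pixel centres at
# integer coordinates. Errors when any point leaves [0, W-1] x [0, H-1].
bilinear_sample <- function(frame, xs, ys) {
  h <- nrow(frame); w <- ncol(frame)
  eps <- 1e-9
  if (any(xs < -eps | xs > (w - 1) + eps | ys < -eps | ys > (h - 1) + eps)) {
    stop("sampling line exits the frame bounds")
  }
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  x0 <- pmin(floor(xs), w - 2); fx <- xs - x0
  y0 <- pmin(floor(ys), h - 2); fy <- ys - y0
  i <- y0 + 1L; j <- x0 + 1L   # to 1-based array indices
  (1 - fx) * (1 - fy) * frame[cbind(i,      j)] +
       fx  * (1 - fy) * frame[cbind(i,      j + 1L)] +
  (1 - fx) *      fy  * frame[cbind(i + 1L, j)] +
       fx  *      fy  * frame[cbind(i + 1L, j + 1L)]
}

#' Smooth a profile with a centred moving average
#'
#' Suppresses pixel noise before differentiation. Ends are padded by edge
#' replication so the length is unchanged and a constant profile passes
#' through untouched.
#'
#' @param p An [intensity_profile()] or numeric vector.
#' @param window Odd window length in samples, \code{1 <= window <=
#'   length/2}. \code{window = 1} is the identity.
#' @return Same type as \code{p}, smoothed.
#' @export
smooth_profile <- function(p, window = 5L) {
  v <- profile_values(p)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L || window > length(v) %/% 2L) {
    stop("`window` must be odd and between 1 and length/2")
  }
  if (window > 1L) {
    h <- window %/% 2L
    padded <- c(rep(v[1L], h), v, rep(v[length(v)], h))
    v <- as.numeric(stats::filter(padded, rep(1 / window, window),
                                  sides = 2L))[(h + 1L):(h + length(profile_values(p)))]
  }
  replace_values(p, v)
}

#' Differentiate a profile (dF/dx)
#'
#' Central differences in the interior, one-sided differences at the two
#' ends; exact for linear ramps everywhere and for quadratics in the
#' interior. Length is unchanged.
#'
#' @param p An [intensity_profile()] or numeric vector of length >= 3.
#' @return Same type as \code{p}, holding dF/dx in intensity units per px.
#' @export
differentiate <- function(p) {
  v <- profile_values(p)
  n <- length(v)
  if (n < 3L) stop("profile too short to differentiate (need >= 3 samples)")
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / 2
  d[1L] <- v[2L] - v[1L]
  d[n] <- v[n] - v[n - 1L]
  replace_values(p, d)
}

profile_values <- function(p) {
  if (inherits(p, "intensity_profile")) p$values else as.numeric(p)
}

replace_values <- function(p, v) {
  if (inherits(p, "intensity_profile")) {
    p$values <- v
    p
  } else {
    v
  }
}

#' Detect peaks in a 1-D signal
#'
#' Finds local maxima strictly greater than their immediate neighbours
#' (plateau maxima report the leftmost plateau sample; signal endpoints are
#' never peaks), filters them by topographic prominence -- the height of the
#' peak above the higher of its two flanking minima -- and greedily
#' suppresses crowded peaks: when two qualifying peaks are closer than
#' \code{min_separation} samples the taller survives, ties going to the
#' leftmost. Results are fully deterministic.
#'
#' @param signal Numeric vector.
#' @param min_prominence Minimum prominence, in signal units (>= 0).
#' @param min_separation Minimum index spacing between reported peaks
#'   (>= 1).
#' @return Increasing integer vector of peak indices (1-based, as usual for
#'   R vectors); may be empty.
#' @examples
#' detect_peaks(c(0, 1, 0), min_prominence = 0.5)       # 2
#' detect_peaks(c(0, 3, 0, 2, 0), min_separation = 3)   # 2
#' @export
detect_peaks <- function(signal, min_prominence = 0, min_separation = 1L) {
  stopifnot(min_prominence >= 0, min_separation >= 1)
  v <- as.numeric(signal)
  n <- length(v)
  if (n < 3L) return(integer(0))

  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  cand <- integer(0)
  if (k >= 3L) {
    for (m in 2:(k - 1L)) {
      if (r$values[m] > r$values[m - 1L] && r$values[m] > r$values[m + 1L]) {
        cand <- c(cand, starts[m])
      }
    }
  }
  if (length(cand) == 0L) return(integer(0))

  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) <= 1L || min_separation <= 1) return(cand)

  ord <- order(-v[cand], cand)   # tallest first, ties leftmost
  kept <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(kept - i) >= min_separation)) kept <- c(kept, i)
  }
  sort(kept)
}

# Topographic prominence of the local maximum at index i: descend on each
# side until a strictly higher sample (or the signal end) is met; the base is
# the higher of the two side minima.
peak_prominence <- function(v, i) {
  h <- v[i]
  left <- h
  j <- i - 1L
  while (j >= 1L && v[j] <= h) {
    if (v[j] < left) left <- v[j]
    j <- j - 1L
  }
  right <- h
  j <- i + 1L
  while (j <= length(v) && v[j] <= h) {
    if (v[j] < right) right <- v[j]
    j <- j + 1L
  }
  h - max(left, right)
}
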