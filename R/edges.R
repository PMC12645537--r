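#' Detection parameters
#'
#' Tunable parameters of the edge detectors, with defaults that work across
#' 8- and 16-bit inputs because the two prominence thresholds are relative
#' (to the robust spread of the derivative and to the profile's dynamic
#' range respectively).
#'
#' @param smooth_window Moving-average window (odd samples) applied before
#'   differentiation; default 5.
#' @param k Derivative prominence multiplier: a derivative peak qualifies as
#'   an edge when its prominence exceeds \code{k} times the robust
#'   (MAD-based) SD of dF/dx; default 3.
#' @param band_prominence Fluorescence/ultrasound wall-band prominence as a
#'   fraction of the profile dynamic range; default 0.25.
#' @param rel_prominence Second qualification for brightfield edge peaks: a
#'   derivative peak must also reach this fraction of the strongest
#'   same-sign peak's prominence, which keeps isolated noise spikes from
#'   posing as the outermost edge; default 0.25.
#' @param min_separation Minimum spacing between detected edges, px;
#'   default 5.
#' @param cnr_min Minimum contrast-to-noise ratio: the profile's dynamic
#'   range (after smoothing) must exceed \code{cnr_min} times a robust
#'   noise estimate from the raw first differences, or the profile is
#'   declared edge-free. This is what makes a frame of pure noise fail
#'   rather than report a spurious full-width vessel; default 6.
#' @param invert Flip the profile sign before detection, for nonstandard
#'   contrast (e.g. inverted video exports); default \code{FALSE}.
#' @return A list of class \code{detect_params}.
#' @export
detect_params <- function(smooth_window = 5L, k = 3, band_prominence = 0.25,
                          rel_prominence = 0.25, min_separation = 5L,
                          cnr_min = 6, invert = FALSE) {
  stopifnot(smooth_window >= 1L, smooth_window %% 2L == 1L, k >= 0,
            band_prominence >= 0, band_prominence <= 1,
            rel_prominence >= 0, rel_prominence <= 1, min_separation >= 1,
            cnr_min >= 0)
  structure(list(smooth_window = as.integer(smooth_window), k = k,
                 band_prominence = band_prominence,
                 rel_prominence = rel_prominence,
                 min_separation = as.integer(min_separation),
                 cnr_min = cnr_min, invert = isTRUE(invert)),
            class = "detect_params")
}

#' Sub-pixel refinement of a peak position
#'
#' Fits a parabola through the three samples around a peak and returns the
#' abscissa of its vertex, clamped to half a sample either side of the peak.
#' A degenerate (zero-curvature) triple, or a peak at the signal boundary,
#' returns \code{peak_index} unchanged.
#'
#' @param signal Numeric vector.
#' @param peak_index Index of a local maximum (1-based).
#' @return Continuous position in the same (1-based) index space.
#' @export
refine_subpixel <- function(signal, peak_index) {
  n <- length(signal)
  i <- as.integer(peak_index)
  if (i <= 1L || i >= n) return(as.numeric(peak_index))
  y0 <- signal[i - 1L]; y1 <- signal[i]; y2 <- signal[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (denom == 0) return(as.numeric(i))
  delta <- (y0 - y2) / (2 * denom)
  i + max(-0.5, min(0.5, delta))
}

#' Vessel edge positions on a single profile
#'
#' An \code{edge_set} holds the sub-pixel positions of the outer-left,
#' inner-left, inner-right and outer-right wall edges along a profile,
#' expressed as distance in px from the first sample (first sample = 0).
#' Inner edges may be absent (\code{NA}); en-face mode never carries them.
#'
#' @param outer_left,outer_right Outer wall edge positions;
#'   \code{outer_left < outer_right}.
#' @param inner_left,inner_right Lumen edge positions or \code{NA}; when
#'   present they must satisfy \code{outer_left < inner_left < inner_right <
#'   outer_right}.
#' @param mode Modality tag.
#' @param bands Optional band-apex positions retained for diagnostics
#'   (fluorescence detector).
#' @return An object of class \code{edge_set}.
#' @export
edge_set <- function(outer_left, outer_right, inner_left = NA_real_,
                     inner_right = NA_real_, mode = "brightfield",
                     bands = NULL) {
  if (!is.finite(outer_left) || !is.finite(outer_right) ||
      outer_left >= outer_right) {
    stop(no_edges_error("outer edges missing or out of order"))
  }
  has_inner <- is.finite(inner_left) && is.finite(inner_right)
  if (has_inner &&
      !(outer_left < inner_left && inner_left < inner_right &&
        inner_right < outer_right)) {
    # refinement can nudge a weak inner candidate past its neighbour;
    # report outer edges only rather than an inconsistent set
    inner_left <- NA_real_
    inner_right <- NA_real_
  }
  structure(list(outer_left = outer_left, inner_left = inner_left,
                 inner_right = inner_right, outer_right = outer_right,
                 mode = mode, bands = bands),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set %s> outer %.3f / %.3f px", x$mode,
              x$outer_left, x$outer_right))
  if (is.finite(x$inner_left)) {
    cat(sprintf(", inner %.3f / %.3f px", x$inner_left, x$inner_right))
  }
  cat("\n")
  invisible(x)
}

# Edge refinement used by the detectors: a derivative peak with a flat top
# (a plateau of tied samples, as a box-smoothed step edge produces) is
# located at the plateau centroid; a single-sample peak falls through to the
# 3-point parabolic vertex. Ties are detected with a relative tolerance so
# floating-point dust does not break a plateau.
refine_edge <- function(signal, peak_index) {
  n <- length(signal)
  i <- as.integer(peak_index)
  tol <- 1e-9 * max(abs(signal), 1)
  a <- i
  while (a > 1L && abs(signal[a - 1L] - signal[i]) <= tol) a <- a - 1L
  b <- i
  while (b < n && abs(signal[b + 1L] - signal[i]) <= tol) b <- b + 1L
  if (b > a) (a + b) / 2 else refine_subpixel(signal, i)
}

no_edges_error <- function(msg) {
  errorCondition(msg, class = c("myographr_no_edges", "myographr_error"))
}

# Contrast-to-noise gate: sigma is estimated robustly from raw first
# differences (mad(diff)/sqrt(2)), to which genuine step edges contribute
# only a handful of samples. A profile whose smoothed dynamic range does not
# clearly exceed that noise level has no credible vessel in it.
check_contrast <- function(v, dyn, params) {
  sigma_hat <- stats::mad(diff(v)) / sqrt(2)
  if (dyn < params$cnr_min * sigma_hat) {
    stop(no_edges_error("insufficient contrast-to-noise ratio"))
  }
  invisible(TRUE)
}

#' Detect vessel wall edges on an intensity profile
#'
#' Dispatches on imaging modality. \code{brightfield} walls are dark on a
#' bright background and are found as peaks in the derivative of the
#' profile; \code{fluorescence} and \code{ultrasound} walls appear as two
#' bright bands on a dark lumen/background and are found by locating the
#' band apexes first and then the steepest point of each flank;
#' \code{en_face} (flat-mounted strip) uses the brightfield detector with
#' inner-diameter detection disabled, since a strip has only two edges.
#'
#' @param p An [intensity_profile()] or numeric vector.
#' @param mode One of \code{"brightfield"}, \code{"fluorescence"},
#'   \code{"ultrasound"}, \code{"en_face"}.
#' @param params A [detect_params()] object.
#' @return An [edge_set()]; positions in px from the first profile sample.
#'   Profiles without a qualifying edge pair raise a condition of class
#'   \code{myographr_no_edges} which callers may trap to hold the last
#'   accepted value.
#' @export
find_edges <- function(p, mode = c("brightfield", "fluorescence",
                                   "ultrasound", "en_face"),
                       params = detect_params()) {
  mode <- match.arg(mode)
  v <- profile_values(p)
  if (isTRUE(params$invert)) v <- -v
  switch(mode,
    brightfield = find_edges_brightfield(v, params),
    fluorescence = find_edges_fluorescence(v, params, mode = "fluorescence"),
    ultrasound = find_edges_fluorescence(v, params, mode = "ultrasound"),
    en_face = find_edges_brightfield(v, params, search_inner = FALSE,
                                     mode = "en_face"))
}

#' @rdname find_edges
#' @param search_inner Look for lumen (inner) edges between the outer pair;
#'   disabled for en-face strips.
#' @export
find_edges_brightfield <- function(p, params = detect_params(),
                                   search_inner = TRUE, mode = "brightfield") {
  v <- profile_values(p)
  s <- smooth_profile(v, params$smooth_window)
  dyn <- diff(range(s))
  if (dyn <= 0) stop(no_edges_error("flat profile: no edges"))
  check_contrast(v, dyn, params)
  d <- differentiate(s)
  floor_prom <- max(params$k * stats::mad(d), 1e-3 * dyn)
  # an edge must clear the noise floor AND hold its own against the
  # strongest edge of the same sign
  qualify <- function(sig) {
    cand <- detect_peaks(sig, floor_prom, params$min_separation)
    if (length(cand) <= 1L) return(cand)
    prom <- vapply(cand, function(i) peak_prominence(sig, i), numeric(1))
    cand[prom >= params$rel_prominence * max(prom)]
  }
  pos <- qualify(d)    # rising edges
  neg <- qualify(-d)   # falling edges
  if (length(neg) == 0L || length(pos) == 0L) {
    stop(no_edges_error("fewer than one qualifying edge per side"))
  }
  ol <- neg[1L]                # leftmost falling: background -> wall
  or <- pos[length(pos)]       # rightmost rising: wall -> background
  if (ol >= or) stop(no_edges_error("outer edges out of order"))

  il <- ir <- NA_real_
  if (search_inner) {
    mid <- (ol + or) / 2
    cl <- pos[pos > ol & pos < mid]   # rising inside left half: wall -> lumen
    cr <- neg[neg > mid & neg < or]   # falling inside right half
    if (length(cl)) il <- refine_edge(d, cl[which.max(d[cl])]) - 1
    if (length(cr)) ir <- refine_edge(-d, cr[which.max(-d[cr])]) - 1
    if (!(is.finite(il) && is.finite(ir))) il <- ir <- NA_real_
  }
  edge_set(outer_left = refine_edge(-d, ol) - 1,
           outer_right = refine_edge(d, or) - 1,
           inner_left = il, inner_right = ir, mode = mode)
}

#' @rdname find_edges
#' @export
find_edges_fluorescence <- function(p, params = detect_params(),
                                    mode = "fluorescence") {
  v <- profile_values(p)
  s <- smooth_profile(v, params$smooth_window)
  dyn <- diff(range(s))
  if (dyn <= 0) stop(no_edges_error("flat profile: no edges"))
  check_contrast(v, dyn, params)
  bands <- detect_peaks(s, params$band_prominence * dyn,
                        params$min_separation)
  if (length(bands) < 2L) {
    stop(no_edges_error("fewer than two wall bands found"))
  }
  L <- bands[1L]
  R <- bands[length(bands)]
  mid <- floor((L + R) / 2)
  d <- differentiate(s)
  n <- length(d)
  argmax_in <- function(sig, from, to) {
    if (from > to) stop(no_edges_error("degenerate band geometry"))
    idx <- from:to
    idx[which.max(sig[idx])]
  }
  ol <- argmax_in(d, 1L, L - 1L)          # outer flank of left band rises
  il <- argmax_in(-d, L + 1L, mid)        # inner flank falls into the lumen
  ir <- argmax_in(d, mid, R - 1L)         # lumen rises into right band
  or <- argmax_in(-d, R + 1L, n)          # outer flank of right band falls
  edge_set(outer_left = refine_edge(d, ol) - 1,
           inner_left = refine_edge(-d, il) - 1,
           inner_right = refine_edge(d, ir) - 1,
           outer_right = refine_edge(-d, or) - 1,
           mode = mode, bands = c(L, R) - 1)
}
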