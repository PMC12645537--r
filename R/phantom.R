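#' Specify a synthetic vessel phantom
#'
#' A phantom is a rendered image stack with exactly known geometry, used as
#' ground truth for every tracking algorithm. Three geometries are
#' supported: a \code{straight} tube crossing the frame at any angle, a
#' \code{branched3} Y-junction of three arms with independent diameter
#' tracks (emulating a triple-cannulated branched artery), and a
#' \code{strip} -- a two-edged flat band emulating an en-face (flat-mounted)
#' preparation. The wall boundary is rendered with a 1-px anti-aliasing ramp
#' centred on the true edge, so that after Gaussian blur the steepest point
#' of the intensity transition falls at the exact analytic edge position and
#' sub-pixel accuracy claims are testable.
#'
#' @param geometry \code{"straight"}, \code{"branched3"} or \code{"strip"}.
#' @param frame_size \code{c(width, height)} in px.
#' @param od_track Ground-truth outer diameter per frame, um: a numeric
#'   vector (straight/strip) or an \code{n_frames x 3} matrix (one column
#'   per arm) for \code{branched3}. For strips this is the strip width.
#' @param id_fraction Inner/outer diameter ratio, in (0, 1); scalar or one
#'   value per frame. Ignored for strips.
#' @param modality Visual appearance preset: \code{"brightfield"} (dark
#'   walls on bright background, grey lumen), \code{"fluorescence"} or
#'   \code{"ultrasound"} (bright wall bands on dark background/lumen),
#'   \code{"en_face"} (dark strip on bright background).
#' @param intensities Optional \code{c(background, wall, lumen)} in
#'   \code{[0, 255]}, overriding the modality preset.
#' @param axis_angle Vessel axis angle, degrees from the +x axis (0 =
#'   horizontal vessel); default 90 (vertical vessel, measured by
#'   horizontal scanlines).
#' @param arm_angles Length-3 arm directions for \code{branched3}, degrees;
#'   default \code{c(90, 210, 330)}.
#' @param psf_sigma Gaussian point-spread-function SD, px; default 0.8.
#' @param noise_sd Additive Gaussian noise SD, intensity units; default 0.
#' @param calibration A [calibration()]; default 0.5 um/px.
#' @param n_frames Number of frames; defaults to the length of
#'   \code{od_track}.
#' @param frame_interval Seconds between frames; default 1.
#' @param seed Integer seed; frame \code{i} (0-based) uses stream
#'   \code{seed + i} so stacks are reproducible frame-wise.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(geometry = c("straight", "branched3", "strip"),
                         frame_size = c(256L, 192L),
                         od_track = 100,
                         id_fraction = 0.6,
                         modality = c("brightfield", "fluorescence",
                                      "ultrasound", "en_face"),
                         intensities = NULL,
                         axis_angle = 90,
                         arm_angles = c(90, 210, 330),
                         psf_sigma = 0.8,
                         noise_sd = 0,
                         calibration = myographr::calibration(0.5),
                         n_frames = NULL,
                         frame_interval = 1,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  modality <- match.arg(modality)
  if (geometry == "branched3") {
    od_track <- as.matrix(od_track)
    if (ncol(od_track) == 1L) od_track <- od_track[, c(1L, 1L, 1L)]
    if (ncol(od_track) != 3L) stop("branched3 needs exactly 3 od_tracks")
    stopifnot(length(arm_angles) == 3L)
  } else {
    od_track <- as.numeric(od_track)
  }
  if (any(od_track <= 0)) stop("od_track must be positive everywhere")
  if (any(id_fraction <= 0) || any(id_fraction >= 1)) {
    stop("id_fraction must lie strictly in (0, 1)")
  }
  if (is.null(n_frames)) n_frames <- NROW(od_track)
  if (NROW(od_track) == 1L) {
    od_track <- if (is.matrix(od_track)) {
      od_track[rep(1L, n_frames), , drop = FALSE]
    } else rep(od_track, n_frames)
  }
  stopifnot(NROW(od_track) == n_frames)
  id_fraction <- rep_len(id_fraction, n_frames)
  if (is.null(intensities)) {
    intensities <- switch(modality,
      brightfield = c(background = 200, wall = 50, lumen = 150),
      fluorescence = c(background = 8, wall = 220, lumen = 8),
      ultrasound = c(background = 12, wall = 210, lumen = 20),
      en_face = c(background = 200, wall = 50, lumen = NA_real_))
  } else {
    intensities <- rep_len(as.numeric(intensities), 3L)
    names(intensities) <- c("background", "wall", "lumen")
  }
  stopifnot(psf_sigma >= 0, noise_sd >= 0,
            inherits(calibration, "calibration"))
  structure(list(geometry = geometry, frame_size = as.integer(frame_size),
                 od_track = od_track, id_fraction = id_fraction,
                 modality = modality, intensities = intensities,
                 axis_angle = axis_angle, arm_angles = arm_angles,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 calibration = calibration, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s %s, %d frames of %d x %d px, %.3g um/px, psf %.2g px, noise sd %.3g\n",
              x$modality, x$geometry, x$n_frames, x$frame_size[1],
              x$frame_size[2], x$calibration$scale, x$psf_sigma, x$noise_sd))
  invisible(x)
}

# Run code with a local, restored RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# coverage of {distance <= half_width} under a 1-px anti-aliasing ramp
aa_coverage <- function(dist, half_width) {
  pmin(pmax(half_width + 0.5 - dist, 0), 1)
}

#' Render one phantom frame
#'
#' @param spec A [phantom_spec()].
#' @param frame_index 0-based frame number, \code{< n_frames}.
#' @return A list with \code{frame} (numeric matrix) and \code{truth} (a
#'   data.frame with one row per arm: \code{frame}, \code{arm},
#'   \code{od_um}, \code{id_um}).
#' @export
render_frame <- function(spec, frame_index) {
  stopifnot(inherits(spec, "phantom_spec"),
            frame_index >= 0, frame_index < spec$n_frames)
  i <- frame_index + 1L
  w <- spec$frame_size[1]; h <- spec$frame_size[2]
  scale <- spec$calibration$scale
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  bg <- spec$intensities[["background"]]
  wall <- spec$intensities[["wall"]]
  lum <- spec$intensities[["lumen"]]

  if (spec$geometry == "branched3") {
    od_px <- spec$od_track[i, ] / scale
    id_px <- od_px * spec$id_fraction[i]
    if (any((od_px - id_px) / 2 < 2)) {
      stop("degenerate phantom: wall thinner than 2 px at this calibration")
    }
    dist <- array(Inf, c(h, w, 3))
    for (a in 1:3) {
      th <- spec$arm_angles[a] * pi / 180
      ux <- cos(th); uy <- sin(th)
      s <- (xs - cx) * ux + (ys - cy) * uy
      r <- abs(-(xs - cx) * uy + (ys - cy) * ux)
      # distance to the half-line (ray) of this arm
      dist[, , a] <- ifelse(s >= 0, r, sqrt(r^2 + s^2))
    }
    flat <- matrix(dist, h * w, 3)
    nearest <- max.col(-flat, ties.method = "first")
    d <- matrix(flat[cbind(seq_len(h * w), nearest)], h, w)
    a_half <- matrix(od_px[nearest] / 2, h, w)
    b_half <- matrix(id_px[nearest] / 2, h, w)
    frame <- bg + (wall - bg) * aa_coverage(d, a_half) +
      (lum - wall) * aa_coverage(d, b_half)
    truth <- data.frame(frame = frame_index, arm = 1:3,
                        od_um = spec$od_track[i, ],
                        id_um = spec$od_track[i, ] * spec$id_fraction[i])
  } else {
    od_px <- spec$od_track[i] / scale
    th <- spec$axis_angle * pi / 180
    d <- abs(-(xs - cx) * sin(th) + (ys - cy) * cos(th))
    if (spec$geometry == "strip") {
      frame <- bg + (wall - bg) * aa_coverage(d, od_px / 2)
      truth <- data.frame(frame = frame_index, arm = 1L,
                          od_um = spec$od_track[i], id_um = NA_real_)
    } else {
      id_px <- od_px * spec$id_fraction[i]
      if ((od_px - id_px) / 2 < 2) {
        stop("degenerate phantom: wall thinner than 2 px at this calibration")
      }
      frame <- bg + (wall - bg) * aa_coverage(d, od_px / 2) +
        (lum - wall) * aa_coverage(d, id_px / 2)
      truth <- data.frame(frame = frame_index, arm = 1L,
                          od_um = spec$od_track[i],
                          id_um = spec$od_track[i] * spec$id_fraction[i])
    }
  }

  if (spec$psf_sigma > 0) {
    frame <- EBImage::gblur(frame, sigma = spec$psf_sigma,
                            boundary = "replicate")
    frame <- matrix(as.numeric(frame), h, w)
  }
  if (spec$noise_sd > 0) {
    frame <- frame + with_seed(spec$seed + frame_index,
                               matrix(stats::rnorm(h * w, 0, spec$noise_sd),
                                      h, w))
  }
  list(frame = frame, truth = truth)
}

#' Render a full phantom stack
#'
#' @param spec A [phantom_spec()].
#' @return A list with \code{stack} (a [frame_stack()]) and \code{truth}
#'   (the row-bound ground truth of every frame).
#' @export
render_stack <- function(spec) {
  out <- lapply(seq_len(spec$n_frames) - 1L, function(f) render_frame(spec, f))
  stack <- frame_stack(lapply(out, `[[`, "frame"),
                       frame_interval = spec$frame_interval,
                       calibration = spec$calibration)
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  rownames(truth) <- NULL
  list(stack = stack, truth = truth)
}

#' Render a branched three-arm phantom with per-arm measurement lines
#'
#' Renders a \code{branched3} phantom and places one perpendicular segment
#' track line across each arm at a standoff distance from the junction,
#' checking that no other arm intrudes into any line's measurement region.
#'
#' @param spec A [phantom_spec()] with \code{geometry = "branched3"}.
#' @param standoff_px Distance from the junction to each measurement line
#'   along its arm, px; default 0.35 of the smaller frame dimension.
#' @param margin_px Extra profile length beyond the largest outer diameter
#'   on each side, px; default 16.
#' @return A list with \code{stack}, \code{truth} (per frame and arm) and
#'   \code{lines} (three [track_line()]s, ids 1-3, one per arm).
#' @export
make_branched_stack <- function(spec, standoff_px = NULL, margin_px = 16) {
  stopifnot(inherits(spec, "phantom_spec"), spec$geometry == "branched3")
  w <- spec$frame_size[1]; h <- spec$frame_size[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  if (is.null(standoff_px)) standoff_px <- 0.35 * min(w, h)
  scale <- spec$calibration$scale
  od_px_max <- apply(as.matrix(spec$od_track), 2, max) / scale

  lines <- vector("list", 3L)
  for (a in 1:3) {
    th <- spec$arm_angles[a] * pi / 180
    ux <- cos(th); uy <- sin(th)
    half_len <- od_px_max[a] / 2 + margin_px
    mx <- cx + ux * standoff_px; my <- cy + uy * standoff_px
    # perpendicular segment centred on the arm axis
    lines[[a]] <- track_line(a, "segment",
                             x0 = mx + uy * half_len, y0 = my - ux * half_len,
                             x1 = mx - uy * half_len, y1 = my + ux * half_len,
                             mode = spec$modality, half_width = 2)
    # no other arm may intrude into this line's measurement region
    for (b in setdiff(1:3, a)) {
      thb <- spec$arm_angles[b] * pi / 180
      for (tt in c(0, 0.5, 1)) {
        px <- mx + uy * half_len * (1 - 2 * tt)
        py <- my - ux * half_len * (1 - 2 * tt)
        s <- (px - cx) * cos(thb) + (py - cy) * sin(thb)
        r <- abs(-(px - cx) * sin(thb) + (py - cy) * cos(thb))
        db <- if (s >= 0) r else sqrt(r^2 + s^2)
        if (db < od_px_max[b] / 2 + 2) {
          stop("geometry error: arm ", b, " overlaps the measurement region ",
               "of arm ", a)
        }
      }
    }
  }
  rendered <- render_stack(spec)
  c(rendered, list(lines = lines))
}

#' Simulate a ground-truth diameter time course
#'
#' Produces the per-frame outer-diameter track fed to a phantom. Two kinds:
#' \describe{
#'   \item{\code{drug_step}}{the diameter relaxes exponentially from its
#'     current value toward a new target after each event (emulating
#'     vasoconstrictor/vasodilator additions), with time constant
#'     \code{tau_s};}
#'   \item{\code{pressure_curve}}{a passive pressure-diameter relation
#'     \code{D0 * (1 - a * exp(-P / Pc))} that saturates at high pressure,
#'     minus (when \code{active = TRUE}) a myogenic tone term that rises
#'     smoothly above a threshold pressure -- emulating arteries that
#'     constrict at pressures above ~60 mmHg.}
#' }
#' These time courses are test fixtures, not physiological models; their
#' parameters are documented as such.
#'
#' @param kind \code{"drug_step"} or \code{"pressure_curve"}.
#' @param params For \code{drug_step}: \code{n_frames}, \code{dt} (s),
#'   \code{start_od} (um), \code{events} (data.frame with \code{time},
#'   \code{target}, optional per-event \code{tau}), \code{tau_s} (default
#'   time constant, s, > 0). For \code{pressure_curve}: \code{pressures}
#'   (mmHg per frame), \code{D0} (um), \code{a}, \code{Pc} (mmHg, > 0),
#'   \code{active} (logical), \code{tone_max} (um), \code{P_threshold},
#'   \code{P_sat} (mmHg).
#' @return Numeric vector: ground-truth OD (um) per frame.
#' @export
simulate_dynamics <- function(kind = c("drug_step", "pressure_curve"),
                              params = list()) {
  kind <- match.arg(kind)
  if (kind == "drug_step") {
    p <- modifyList(list(n_frames = 100L, dt = 1, start_od = 150,
                         events = NULL, tau_s = 10), params)
    if (p$tau_s <= 0) stop("`tau_s` must be positive")
    od <- numeric(p$n_frames)
    cur <- p$start_od
    target <- p$start_od
    tau <- p$tau_s
    ev <- p$events
    if (!is.null(ev)) {
      ev <- ev[order(ev$time), , drop = FALSE]
      if (!is.null(ev$tau) && any(ev$tau <= 0)) stop("`tau` must be positive")
    }
    nxt <- 1L
    for (f in seq_len(p$n_frames)) {
      t <- (f - 1L) * p$dt
      while (!is.null(ev) && nxt <= nrow(ev) && ev$time[nxt] <= t) {
        target <- ev$target[nxt]
        if (!is.null(ev$tau)) tau <- ev$tau[nxt]
        nxt <- nxt + 1L
      }
      od[f] <- cur
      cur <- target + (cur - target) * exp(-p$dt / tau)
    }
    od
  } else {
    p <- modifyList(list(pressures = seq(20, 100, by = 5), D0 = 200,
                         a = 0.5, Pc = 40, active = FALSE, tone_max = 40,
                         P_threshold = 60, P_sat = 140), params)
    if (p$Pc <= 0) stop("`Pc` must be positive")
    passive <- p$D0 * (1 - p$a * exp(-p$pressures / p$Pc))
    if (!isTRUE(p$active)) return(passive)
    passive - myogenic_tone(p$pressures, p$tone_max, p$P_threshold, p$P_sat)
  }
}

# Smooth tone ramp: exactly 0 at/below the threshold, strictly positive
# above it, saturating at tone_max by P_sat (cubic smoothstep).
myogenic_tone <- function(P, tone_max, P_threshold, P_sat) {
  t <- pmin(pmax((P - P_threshold) / (P_sat - P_threshold), 0), 1)
  tone_max * t^2 * (3 - 2 * t)
}
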