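#' Read a session configuration file
#'
#' Sessions are configured in a plain-text YAML file holding the
#' calibration (either a direct \code{scale} in um/px, or
#' \code{camera_pixel_um} + \code{magnification}, or the name of an entry in
#' a \code{calibrations:} block so rigs can store their scaling factors once
#' and switch quickly), the track-line definitions (at most five), the
#' detection and temporal-filter parameters, an optional pressure protocol
#' and phantom block for simulated experiments, and the seed that every
#' source of randomness flows from.
#'
#' @param path YAML file path.
#' @return A list of class \code{session_config} with resolved objects:
#'   \code{calibration}, \code{lines}, \code{detect}, \code{track},
#'   \code{protocol}, \code{servo}, \code{phantom}, \code{dynamics},
#'   \code{frame_interval}, \code{seed}.
#' @export
read_session_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  session_config(cfg)
}

#' @rdname read_session_config
#' @param cfg A list with the same structure as the YAML file (useful for
#'   building configs programmatically).
#' @export
session_config <- function(cfg) {
  cal <- resolve_calibration(cfg)
  lines <- NULL
  if (!is.null(cfg$lines)) {
    if (length(cfg$lines) > 5L) stop("at most 5 track lines per session")
    lines <- lapply(cfg$lines, function(l) {
      # YAML 1.1 reads a bare `y` key as the boolean TRUE; restore it
      names(l)[names(l) == "TRUE"] <- "y"
      do.call(track_line, l)
    })
  }
  detect <- do.call(detect_params, as.list(cfg$detection))
  track <- do.call(track_params, as.list(cfg$tracking))
  protocol <- if (!is.null(cfg$protocol)) {
    do.call(pressure_protocol, cfg$protocol)
  }
  servo <- if (!is.null(cfg$servo)) {
    do.call(simulated_servo, cfg$servo)
  } else {
    simulated_servo()
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  frame_interval <- if (is.null(cfg$frame_interval)) 1 else cfg$frame_interval
  phantom <- NULL
  if (!is.null(cfg$phantom)) {
    args <- cfg$phantom
    if (!is.null(args$frame_size)) args$frame_size <- unlist(args$frame_size)
    if (!is.null(args$od_track)) args$od_track <- unlist(args$od_track)
    args$calibration <- cal
    args$seed <- seed
    args$frame_interval <- frame_interval
    phantom <- do.call(phantom_spec, args)
  }
  structure(list(calibration = cal, lines = lines, detect = detect,
                 track = track, protocol = protocol, servo = servo,
                 phantom = phantom, dynamics = cfg$dynamics,
                 frame_interval = frame_interval, seed = seed),
            class = "session_config")
}

resolve_calibration <- function(cfg) {
  cc <- cfg$calibration
  if (is.null(cc)) stop("config must resolve a calibration")
  if (is.character(cc)) {
    store <- cfg$calibrations
    if (is.null(store[[cc]])) {
      stop("named calibration '", cc, "' not found in `calibrations:` block")
    }
    name <- cc
    cc <- store[[cc]]
    cc$label <- name
  }
  if (!is.null(cc$scale)) {
    calibration(cc$scale, cc$camera_pixel_um, cc$magnification,
                label = cc$label %||% "")
  } else {
    make_calibration(cc$camera_pixel_um, cc$magnification,
                     label = cc$label %||% "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a pre-recorded stack end to end
#'
#' Reads a multipage TIFF, tracks every configured line, and writes the
#' two-file CSV results plus an overlay stack with tracking indicators.
#'
#' @param stack_path Path to the input TIFF.
#' @param config A \code{session_config} (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @param base Output file base name; default the stack file name.
#' @return The [result_table()], invisibly. Per-status record counts are
#'   reported via \code{message()}.
#' @export
analyze_session <- function(stack_path, config, out_dir, base = NULL) {
  if (is.character(config)) config <- read_session_config(config)
  if (is.null(config$lines)) stop("config defines no track lines")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(base)) base <- sub("\\.tiff?$", "", basename(stack_path))
  stack <- read_stack(stack_path, config$frame_interval, config$calibration)
  tab <- track_stack(stack, config$lines, config$detect, config$track)
  st <- table(factor(tab$records$status,
                     levels = c("tracked", "held", "failed")))
  message(sprintf("analyzed %d frames x %d lines: %d tracked, %d held, %d failed",
                  length(stack$frames), length(config$lines),
                  st[["tracked"]], st[["held"]], st[["failed"]]))
  base_path <- file.path(out_dir, base)
  write_results_csv(tab, base_path)
  write_overlay(stack, tab, config$lines, paste0(base_path, "_overlay.tiff"))
  invisible(tab)
}

#' Simulate a phantom experiment to disk
#'
#' Renders the configured phantom (applying a \code{dynamics} block, when
#' present, to generate the diameter time course) and writes a multipage
#' TIFF plus a ground-truth CSV (\code{frame, arm, od_um, id_um}).
#'
#' @param config A \code{session_config} (or YAML path) with a
#'   \code{phantom} block.
#' @param out_dir Output directory.
#' @param base Output base name; default \code{"phantom"}.
#' @return Paths of the TIFF and CSV, invisibly.
#' @export
simulate_session <- function(config, out_dir, base = "phantom") {
  if (is.character(config)) config <- read_session_config(config)
  spec <- config$phantom
  if (is.null(spec)) stop("config defines no phantom")
  # a dynamics block drives the diameter track only when it names its kind;
  # otherwise it is left for `protocol_session` (pressure_curve) and the
  # phantom's own od_track is rendered as given
  if (!is.null(config$dynamics) && !is.null(config$dynamics$kind)) {
    dyn <- config$dynamics
    kind <- dyn$kind
    dyn$kind <- NULL
    if (!is.null(dyn$events)) {
      dyn$events <- do.call(rbind, lapply(dyn$events, as.data.frame))
    }
    od <- simulate_dynamics(kind, dyn)
    spec <- phantom_spec(geometry = spec$geometry,
                         frame_size = spec$frame_size, od_track = od,
                         id_fraction = spec$id_fraction[1],
                         modality = spec$modality,
                         intensities = spec$intensities,
                         axis_angle = spec$axis_angle,
                         arm_angles = spec$arm_angles,
                         psf_sigma = spec$psf_sigma,
                         noise_sd = spec$noise_sd,
                         calibration = spec$calibration,
                         frame_interval = spec$frame_interval,
                         seed = spec$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rendered <- if (spec$geometry == "branched3") {
    make_branched_stack(spec)
  } else {
    render_stack(spec)
  }
  tiff_path <- file.path(out_dir, paste0(base, ".tiff"))
  csv_path <- file.path(out_dir, paste0(base, "_truth.csv"))
  write_stack(rendered$stack, tiff_path)
  utils::write.table(rendered$truth, csv_path, sep = ",", row.names = FALSE,
                     na = "", qmethod = "double", fileEncoding = "UTF-8")
  message(sprintf("simulated %d frames (%s %s) -> %s",
                  spec$n_frames, spec$modality, spec$geometry, tiff_path))
  invisible(c(tiff_path, csv_path))
}

#' Run a simulated pressure-protocol experiment to disk
#'
#' @param config A \code{session_config} (or YAML path) with \code{protocol}
#'   and \code{phantom} blocks.
#' @param out_dir Output directory.
#' @param base Output base name; default \code{"protocol"}.
#' @return The two CSV paths, invisibly.
#' @export
protocol_session <- function(config, out_dir, base = "protocol") {
  if (is.character(config)) config <- read_session_config(config)
  if (is.null(config$protocol)) stop("config defines no protocol")
  if (is.null(config$phantom)) stop("config defines no phantom")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dynamics <- as.list(config$dynamics)
  dynamics$kind <- NULL
  tab <- run_protocol(config$protocol, config$servo, dynamics,
                      config$phantom,
                      line = if (!is.null(config$lines)) config$lines[[1]],
                      params = config$detect, track = config$track,
                      dt = config$frame_interval, seed = config$seed)
  message(sprintf("protocol run: %d records, %d pressure events",
                  nrow(tab$records), nrow(tab$events)))
  invisible(write_results_csv(tab, file.path(out_dir, base)))
}
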