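#' Temporal quality-control parameters
#'
#' @param k_frames Rolling-median window (frames) over previously accepted
#'   values; default 5.
#' @param max_jump_fraction Maximum allowed deviation of a new value from
#'   that rolling median, as a fraction of the median; default 0.25. Larger
#'   jumps (and failed detections) carry the last accepted value forward
#'   with status \code{held}.
#' @return A list of class \code{track_params}.
#' @export
track_params <- function(k_frames = 5L, max_jump_fraction = 0.25) {
  stopifnot(k_frames >= 1L, max_jump_fraction > 0)
  structure(list(k_frames = as.integer(k_frames),
                 max_jump_fraction = max_jump_fraction),
            class = "track_params")
}

empty_record <- function(frame_index, time, line_id, status) {
  data.frame(frame = as.integer(frame_index), time_s = time,
             line_id = as.integer(line_id),
             outer_um = NA_real_, inner_um = NA_real_, wall_um = NA_real_,
             n_profiles_used = 0L, status = status,
             outer_left_px = NA_real_, inner_left_px = NA_real_,
             inner_right_px = NA_real_, outer_right_px = NA_real_,
             pressure_mmHg = NA_real_, temperature_C = NA_real_,
             stringsAsFactors = FALSE)
}

#' Measure vessel diameter along one track line in one frame
#'
#' Extracts every scanline profile of the line, detects wall edges on each,
#' and aggregates the per-profile measurements robustly: profiles whose
#' outer diameter deviates from the per-line median by more than 3 times the
#' MAD are discarded (this is what lets a region of interest straddle a
#' side-branch or adherent tissue without corrupting the measurement), and
#' the survivors are combined by median. Segment lines average their
#' \code{2 * half_width + 1} parallel profiles into a single profile before
#' detection. The record is \code{tracked} when at least half of the
#' attempted profiles survive, \code{failed} otherwise.
#'
#' @param frame Numeric intensity matrix.
#' @param line A [track_line()].
#' @param cal A [calibration()].
#' @param params A [detect_params()].
#' @param frame_index,time Frame number (0-based) and time stamp (s) stored
#'   in the record.
#' @return A one-row data.frame (a diameter record) with columns
#'   \code{frame}, \code{time_s}, \code{line_id}, \code{outer_um},
#'   \code{inner_um}, \code{wall_um}, \code{n_profiles_used}, \code{status}
#'   and the aggregated sub-pixel edge positions (px along the line).
#'   \code{inner_um} and \code{wall_um} are \code{NA} when no inner edges
#'   were found (e.g. en-face mode).
#' @export
measure_line <- function(frame, line, cal, params = detect_params(),
                         frame_index = 0L, time = 0) {
  stopifnot(inherits(line, "track_line"), inherits(cal, "calibration"))
  offsets <- scan_offsets(line)

  if (line$kind == "segment") {
    vals <- lapply(offsets, function(o) {
      profile_values(extract_profile(frame, line, o))
    })
    profiles <- list(Reduce(`+`, vals) / length(vals))
  } else {
    profiles <- lapply(offsets, function(o) {
      profile_values(extract_profile(frame, line, o))
    })
  }
  n_attempted <- length(profiles)

  edges <- lapply(profiles, function(v) {
    tryCatch(find_edges(v, line$mode, params),
             myographr_no_edges = function(e) NULL)
  })
  ok <- !vapply(edges, is.null, logical(1))
  if (!any(ok)) {
    return(empty_record(frame_index, time, line$id, "failed"))
  }
  es <- edges[ok]
  od <- vapply(es, function(e) e$outer_right - e$outer_left, numeric(1))
  id <- vapply(es, function(e) e$inner_right - e$inner_left, numeric(1))
  wall <- vapply(es, function(e) {
    ((e$inner_left - e$outer_left) + (e$outer_right - e$inner_right)) / 2
  }, numeric(1))

  med <- stats::median(od)
  keep <- abs(od - med) <= 3 * stats::mad(od) + 1e-6
  ns <- sum(keep)
  status <- if (ns >= ceiling(n_attempted / 2)) "tracked" else "failed"
  if (status == "failed") {
    rec <- empty_record(frame_index, time, line$id, "failed")
    rec$n_profiles_used <- ns
    return(rec)
  }

  agg <- function(x) {
    x <- x[keep][is.finite(x[keep])]
    if (length(x)) stats::median(x) else NA_real_
  }
  outer_px <- agg(od)
  inner_px <- agg(id)
  wall_px <- agg(wall)
  data.frame(frame = as.integer(frame_index), time_s = time,
             line_id = line$id,
             outer_um = px_to_um(cal, outer_px),
             inner_um = if (is.finite(inner_px)) px_to_um(cal, inner_px) else NA_real_,
             wall_um = if (is.finite(wall_px)) px_to_um(cal, wall_px) else NA_real_,
             n_profiles_used = ns, status = status,
             outer_left_px = agg(vapply(es, `[[`, numeric(1), "outer_left")),
             inner_left_px = agg(vapply(es, `[[`, numeric(1), "inner_left")),
             inner_right_px = agg(vapply(es, `[[`, numeric(1), "inner_right")),
             outer_right_px = agg(vapply(es, `[[`, numeric(1), "outer_right")),
             pressure_mmHg = NA_real_, temperature_C = NA_real_,
             stringsAsFactors = FALSE)
}

#' Track a whole image stack
#'
#' Runs [measure_line()] for every frame and every track line, then applies
#' a temporal quality-control filter per line: a tracked value deviating
#' from the rolling median of the previous \code{k_frames} accepted values
#' by more than \code{max_jump_fraction} of that median -- or a failed
#' detection -- does not enter the trace; instead the last accepted value is
#' carried forward with status \code{held}. The first frame is always
#' accepted when tracked.
#'
#' @param stack A [frame_stack()].
#' @param lines A [track_line()] or list of up to five of them, with
#'   distinct ids.
#' @param params A [detect_params()].
#' @param track A [track_params()].
#' @return A [result_table()] whose records are ordered by
#'   \code{(frame, line_id)}; \code{time_s = frame * frame_interval}.
#' @export
track_stack <- function(stack, lines, params = detect_params(),
                        track = track_params()) {
  stopifnot(inherits(stack, "frame_stack"))
  if (inherits(lines, "track_line")) lines <- list(lines)
  if (length(lines) < 1L) stop("at least one track line is required")
  if (length(lines) > 5L) stop("at most 5 track lines per session")
  ids <- vapply(lines, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("track line ids must be distinct")
  if (length(stack$frames) == 0L) stop("empty stack")

  state <- lapply(lines, function(l) list(accepted = numeric(0), last = NULL))
  names(state) <- as.character(ids)
  out <- vector("list", length(stack$frames) * length(lines))
  idx <- 0L
  for (f in seq_along(stack$frames)) {
    t <- (f - 1L) * stack$frame_interval
    for (li in seq_along(lines)) {
      line <- lines[[li]]
      key <- as.character(line$id)
      rec <- measure_line(stack$frames[[f]], line, stack$calibration,
                          params, frame_index = f - 1L, time = t)
      st <- state[[key]]
      if (rec$status == "tracked") {
        accept <- TRUE
        if (length(st$accepted) > 0L) {
          roll <- stats::median(utils::tail(st$accepted, track$k_frames))
          if (abs(rec$outer_um - roll) > track$max_jump_fraction * roll) {
            accept <- FALSE
          }
        }
        if (accept) {
          st$accepted <- c(st$accepted, rec$outer_um)
          st$last <- rec
        } else {
          rec <- hold_record(st$last, f - 1L, t)
        }
      } else if (!is.null(st$last)) {
        rec <- hold_record(st$last, f - 1L, t)
      }
      state[[key]] <- st
      idx <- idx + 1L
      out[[idx]] <- rec
    }
  }
  records <- do.call(rbind, out)
  records <- records[order(records$frame, records$line_id), , drop = FALSE]
  rownames(records) <- NULL
  result_table(records)
}

hold_record <- function(last, frame_index, time) {
  rec <- last
  rec$frame <- as.integer(frame_index)
  rec$time_s <- time
  rec$status <- "held"
  rec
}

#' Equivalent diameter of a flat-mounted (en-face) strip
#'
#' An en-face preparation exposes only the strip width between its two
#' edges. Two reporting conventions are offered: \code{"width"} (default)
#' reports the measured width unchanged; \code{"circumference"} reads the
#' strip width as the unrolled circumference of the intact vessel and
#' reports \code{width / pi}.
#'
#' @param width_um Measured strip width, um; positive.
#' @param convention \code{"width"} or \code{"circumference"}.
#' @return Equivalent diameter, um.
#' @export
equivalent_diameter <- function(width_um,
                                convention = c("width", "circumference")) {
  convention <- match.arg(convention)
  if (any(!is.finite(width_um)) || any(width_um <= 0)) {
    stop("`width_um` must be positive")
  }
  if (convention == "width") width_um else width_um / pi
}

#' Summarise vascular reactivity as a percent diameter change
#'
#' Computes \code{100 * (peak(response) - mean(baseline)) / mean(baseline)}
#' over two non-overlapping time windows of a diameter trace, the standard
#' readout of flow-mediated dilatation and drug-response experiments. The
#' peak is the maximum of the response window for a dilatation and the
#' minimum for a constriction.
#'
#' @param trace A data.frame with columns \code{time_s} and the value column
#'   (plus optionally \code{status}, in which case only \code{tracked}
#'   records are used) -- e.g. the records of a [result_table()].
#' @param baseline_window,response_window Length-2 numeric vectors
#'   \code{c(t0, t1)} in seconds, inclusive, non-overlapping.
#' @param direction \code{"dilatation"} or \code{"constriction"}.
#' @param value_col Column to summarise; default \code{"outer_um"}.
#' @return Percent change (a single number; negative for constrictions).
#' @export
summarize_reactivity <- function(trace, baseline_window, response_window,
                                 direction = c("dilatation", "constriction"),
                                 value_col = "outer_um") {
  direction <- match.arg(direction)
  stopifnot(length(baseline_window) == 2L, length(response_window) == 2L)
  if (baseline_window[1] <= response_window[2] &&
      response_window[1] <= baseline_window[2]) {
    stop("baseline and response windows must not overlap")
  }
  if (!is.null(trace$status)) trace <- trace[trace$status == "tracked", ]
  in_win <- function(w) {
    v <- trace[[value_col]][trace$time_s >= w[1] & trace$time_s <= w[2]]
    v <- v[is.finite(v)]
    if (length(v) == 0L) stop("window contains no tracked records")
    v
  }
  base <- mean(in_win(baseline_window))
  resp <- in_win(response_window)
  peak <- if (direction == "dilatation") max(resp) else min(resp)
  100 * (peak - base) / base
}
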