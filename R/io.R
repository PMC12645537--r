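#' Result table: diameter records plus a timestamped event log
#'
#' The central results container: one row per (frame, line) with the
#' measured diameters and tracking status, and an event log of experimental
#' annotations (drug additions, pressure steps) with optional pressure and
#' temperature readings.
#'
#' @param records Data.frame of diameter records as produced by
#'   [measure_line()] / [track_stack()]; at most one row per
#'   \code{(frame, line_id)} pair.
#' @param events Optional data.frame with columns \code{time_s},
#'   \code{label} and optional \code{pressure_mmHg}, \code{temperature_C};
#'   event times must be non-decreasing.
#' @return An object of class \code{result_table}.
#' @export
result_table <- function(records, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(time_s = numeric(0), label = character(0),
                         pressure_mmHg = numeric(0),
                         temperature_C = numeric(0),
                         stringsAsFactors = FALSE)
  }
  tab <- structure(list(records = records, events = events),
                   class = "result_table")
  validate_result_table(tab)
  tab
}

validate_result_table <- function(tab) {
  r <- tab$records
  if (nrow(r) && anyDuplicated(r[, c("frame", "line_id")])) {
    stop("at most one record per (frame, line_id)")
  }
  e <- tab$events
  if (nrow(e) > 1L && any(diff(e$time_s) < 0)) {
    stop("event times must be non-decreasing")
  }
  invisible(tab)
}

#' @export
print.result_table <- function(x, ...) {
  st <- table(factor(x$records$status,
                     levels = c("tracked", "held", "failed")))
  cat(sprintf("<result_table> %d records (%d tracked, %d held, %d failed), %d events\n",
              nrow(x$records), st[["tracked"]], st[["held"]], st[["failed"]],
              nrow(x$events)))
  invisible(x)
}

#' Append an event to a result table
#'
#' @param tab A [result_table()].
#' @param time_s Event time, s (must not precede the last event).
#' @param label Event text (e.g. drug name, "pressure set").
#' @param pressure_mmHg,temperature_C Optional sensor readings.
#' @return The updated \code{result_table}.
#' @export
add_event <- function(tab, time_s, label, pressure_mmHg = NA_real_,
                      temperature_C = NA_real_) {
  stopifnot(inherits(tab, "result_table"))
  tab$events <- rbind(tab$events,
                      data.frame(time_s = time_s, label = label,
                                 pressure_mmHg = pressure_mmHg,
                                 temperature_C = temperature_C,
                                 stringsAsFactors = FALSE))
  validate_result_table(tab)
  tab
}

results_csv_columns <- c("time_s", "frame", "line_id", "outer_um",
                         "inner_um", "wall_um", "status", "pressure_mmHg",
                         "temperature_C")

#' Write results in the two-file CSV convention
#'
#' Every analysis produces two CSV files: \code{<base>_results.csv} with one
#' row per diameter record (columns \code{time_s, frame, line_id, outer_um,
#' inner_um, wall_um, status, pressure_mmHg, temperature_C}; absent values
#' are empty fields, not zeros) and \code{<base>_table.csv} with the event
#' log (\code{time_s, label, value}, where \code{value} is the pressure
#' reading when present, otherwise the temperature). RFC 4180 quoting, '.'
#' decimal separator, UTF-8.
#'
#' @param tab A [result_table()].
#' @param base_path Output path prefix (without extension).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_results_csv <- function(tab, base_path) {
  stopifnot(inherits(tab, "result_table"))
  validate_result_table(tab)
  f1 <- paste0(base_path, "_results.csv")
  f2 <- paste0(base_path, "_table.csv")
  r <- tab$records[, results_csv_columns, drop = FALSE]
  utils::write.table(r, f1, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double", fileEncoding = "UTF-8")
  e <- tab$events
  value <- ifelse(is.finite(e$pressure_mmHg), e$pressure_mmHg,
                  ifelse(is.finite(e$temperature_C), e$temperature_C,
                         NA_real_))
  ev <- data.frame(time_s = e$time_s, label = e$label, value = value,
                   stringsAsFactors = FALSE)
  utils::write.table(ev, f2, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double", fileEncoding = "UTF-8")
  invisible(c(f1, f2))
}

#' Read back a two-file CSV result set
#'
#' @param base_path The prefix given to [write_results_csv()].
#' @return A [result_table()] (numeric fields restored; edge-position
#'   columns, which are not exported, come back as \code{NA}).
#' @export
read_results_csv <- function(base_path) {
  f1 <- paste0(base_path, "_results.csv")
  f2 <- paste0(base_path, "_table.csv")
  r <- utils::read.csv(f1, stringsAsFactors = FALSE)
  ev <- utils::read.csv(f2, stringsAsFactors = FALSE)
  r$outer_left_px <- r$inner_left_px <- NA_real_
  r$inner_right_px <- r$outer_right_px <- NA_real_
  r$n_profiles_used <- NA_integer_
  events <- data.frame(time_s = as.numeric(ev$time_s),
                       label = as.character(ev$label),
                       pressure_mmHg = if (nrow(ev)) as.numeric(ev$value) else numeric(0),
                       temperature_C = rep(NA_real_, nrow(ev)),
                       stringsAsFactors = FALSE)
  result_table(r, events)
}

#' Read a multipage TIFF stack
#'
#' Reads an 8- or 16-bit grayscale or RGB multipage TIFF, preserving page
#' order and raw integer pixel values. RGB pages are converted to grayscale
#' by the Rec. 601 luminance \code{0.299 R + 0.587 G + 0.114 B} (the
#' standard for video exports such as B-mode ultrasound clips).
#'
#' @param path TIFF file path.
#' @param frame_interval Seconds between frames.
#' @param calibration A [calibration()].
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, frame_interval, calibration) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) {
                      stop("input error: cannot read TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      # multichannel pages come back normalised to [0, 1]: restore the
      # integer code range before collapsing to luminance
      bits <- attr(p, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      p <- p * (2^bits[1] - 1)
      if (dim(p)[3] >= 3L) {
        0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
      } else {
        p[, , 1]
      }
    } else {
      structure(as.numeric(p), dim = dim(p))  # drop TIFF info attributes
    }
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    stop("input error: TIFF pages have inconsistent sizes")
  }
  frame_stack(frames, frame_interval, calibration, source_path = path)
}

#' Write a stack as a multipage TIFF
#'
#' @param x A [frame_stack()] or list of numeric matrices with values in
#'   \code{[0, 2^bits - 1]}.
#' @param path Output file path.
#' @param bits Bits per sample, 8 or 16.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(x, path, bits = 8L) {
  frames <- if (inherits(x, "frame_stack")) x$frames else x
  stopifnot(bits %in% c(8L, 16L))
  top <- 2^bits - 1
  # the TIFF writer truncates value * top: offset rounded integers by half a
  # code so every integer level round-trips exactly
  pages <- lapply(frames, function(f) {
    pmin((round(pmin(pmax(f, 0), top)) + 0.5) / top, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# Pixel indices (1-based, into a h x w matrix) painted by line axes and by
# outer/inner edge tick marks for one frame. Returns a list of integer
# index vectors: $line, $outer, $inner.
overlay_indices <- function(dim_hw, lines, records) {
  h <- dim_hw[1]; w <- dim_hw[2]
  rasterize <- function(xs, ys) {
    i <- round(ys) + 1L; j <- round(xs) + 1L
    keep <- i >= 1L & i <= h & j >= 1L & j <= w
    unique((j[keep] - 1L) * h + i[keep])
  }
  line_idx <- integer(0); outer_idx <- integer(0); inner_idx <- integer(0)
  for (line in lines) {
    mid <- if (line$kind == "segment") 0 else (line$n_scanlines + 1L) / 2
    sl <- scanline_geometry(line, if (line$kind == "segment") 0 else
                            max(1L, round(mid)))
    t <- seq(0, sl$length, by = 0.5)
    line_idx <- c(line_idx, rasterize(sl$x0 + sl$dx * t, sl$y0 + sl$dy * t))
    rec <- records[records$line_id == line$id, , drop = FALSE]
    if (nrow(rec) != 1L || rec$status == "failed") next
    tick <- function(pos) {
      if (!is.finite(pos)) return(integer(0))
      cxp <- sl$x0 + sl$dx * pos; cyp <- sl$y0 + sl$dy * pos
      off <- seq(-3, 3, by = 0.5)
      rasterize(cxp - sl$dy * off, cyp + sl$dx * off)
    }
    outer_idx <- c(outer_idx, tick(rec$outer_left_px), tick(rec$outer_right_px))
    inner_idx <- c(inner_idx, tick(rec$inner_left_px), tick(rec$inner_right_px))
  }
  list(line = unique(line_idx), outer = unique(outer_idx),
       inner = unique(inner_idx))
}

#' Write an overlay stack with tracking indicators
#'
#' Copies the raw stack and draws, on every frame, each track line plus
#' tick marks at the measured outer and inner edge positions; outer and
#' inner indicators use distinct gray levels (255 and 64; the line axis is
#' 128) so they remain distinguishable in grayscale. Pixels not covered by
#' an indicator are left untouched. Failed frames show the line but no
#' ticks.
#'
#' @param stack A [frame_stack()].
#' @param tab A [result_table()] covering the stack's frames.
#' @param lines The [track_line()] list used for tracking.
#' @param path Output TIFF path.
#' @param bits Bits per sample of the output (default 8).
#' @return \code{path}, invisibly.
#' @export
write_overlay <- function(stack, tab, lines, path, bits = 8L) {
  stopifnot(inherits(stack, "frame_stack"), inherits(tab, "result_table"))
  if (inherits(lines, "track_line")) lines <- list(lines)
  if (nrow(tab$records) &&
      max(tab$records$frame) >= length(stack$frames)) {
    stop("result table refers to frames beyond the stack")
  }
  top <- 2^bits - 1
  frames <- lapply(seq_along(stack$frames), function(f) {
    fr <- stack$frames[[f]]
    rec <- tab$records[tab$records$frame == f - 1L, , drop = FALSE]
    if (nrow(rec) == 0L) return(fr)
    idx <- overlay_indices(dim(fr), lines, rec)
    fr[idx$line] <- top / 2 + 0.5
    fr[idx$inner] <- top / 4
    fr[idx$outer] <- top
    fr
  })
  write_stack(frames, path, bits = bits)
}
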