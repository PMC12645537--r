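test_that("TIFF stacks round trip through write_stack/read_stack", {
  cal <- calibration(0.5)
  set.seed(21)
  frames <- lapply(1:5, function(i) {
    matrix(sample(0:255, 30 * 40, TRUE), 30, 40)
  })
  st <- frame_stack(lapply(frames, `+`, 0), 0.5, cal)
  path <- tempfile(fileext = ".tiff")
  write_stack(st, path)
  back <- read_stack(path, 0.5, cal)
  expect_equal(length(back), 5L)
  for (i in 1:5) expect_equal(back$frames[[i]], frames[[i]] + 0)
  expect_equal(back$frame_interval, 0.5)

  # 16-bit values survive too
  f16 <- matrix(sample(0:65535, 300, TRUE), 15, 20)
  p16 <- tempfile(fileext = ".tiff")
  write_stack(list(f16), p16, bits = 16L)
  expect_equal(read_stack(p16, 1, cal)$frames[[1]], f16)
})

test_that("RGB pages collapse to Rec. 601 luminance", {
  # neutral RGB ramp: luminance equals any channel
  g <- matrix(rep(0:19 * 12, each = 10), 10, 20) / 255
  rgb <- array(c(g, g, g), c(10, 20, 3))
  path <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  st <- read_stack(path, 1, calibration(1))
  expect_equal(st$frames[[1]], round(g * 255), tolerance = 1e-9)
  # a saturated red page maps to 0.299 * R
  red <- array(0, c(10, 20, 3)); red[, , 1] <- 1
  tiff::writeTIFF(red, path, bits.per.sample = 8L)
  expect_true(all(abs(read_stack(path, 1, calibration(1))$frames[[1]] -
                      0.299 * 255) < 1e-9))
})

test_that("inconsistent page sizes are an input error", {
  path <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(list(matrix(0.5, 10, 10), matrix(0.5, 12, 10)), path)
  expect_error(read_stack(path, 1, calibration(1)), "inconsistent")
})

make_demo_table <- function() {
  recs <- do.call(rbind, lapply(0:4, function(f) {
    do.call(rbind, lapply(1:2, function(l) {
      r <- myographr:::empty_record(f, f * 0.5, l, "tracked")
      r$outer_um <- 100 + f + l / 10
      r$inner_um <- if (l == 1) 60 + f else NA_real_
      r$wall_um <- if (l == 1) (r$outer_um - r$inner_um) / 2 else NA_real_
      r$n_profiles_used <- 10L
      r
    }))
  }))
  tab <- result_table(recs)
  tab <- add_event(tab, 0.5, "pressure set", pressure_mmHg = 60)
  add_event(tab, 1.5, "phenylephrine 1 uM")
}

test_that("two-file CSV export matches the documented layout and round trips", {
  tab <- make_demo_table()
  base <- tempfile()
  paths <- write_results_csv(tab, base)
  expect_equal(basename(paths),
               paste0(basename(base), c("_results.csv", "_table.csv")))
  l1 <- readLines(paths[1]); l2 <- readLines(paths[2])
  expect_length(l1, 11L)  # header + 10 records
  expect_length(l2, 3L)   # header + 2 events
  expect_equal(l1[1], paste0("\"time_s\",\"frame\",\"line_id\",\"outer_um\",",
                             "\"inner_um\",\"wall_um\",\"status\",",
                             "\"pressure_mmHg\",\"temperature_C\""))
  # absent inner edges export as empty fields, not zeros
  expect_match(l1[3], ",,,\"tracked\"", fixed = TRUE)
  # event without a sensor reading has an empty value field
  expect_match(l2[3], "uM\",$")

  back <- read_results_csv(base)
  for (col in c("time_s", "frame", "line_id", "outer_um", "inner_um",
                "wall_um")) {
    expect_equal(back$records[[col]], tab$records[[col]], tolerance = 1e-6)
  }
  expect_identical(back$records$status, tab$records$status)
  expect_identical(back$events$label, tab$events$label)
  expect_equal(back$events$time_s, tab$events$time_s, tolerance = 1e-6)
})

test_that("result tables enforce uniqueness and event ordering", {
  tab <- make_demo_table()
  expect_error(result_table(rbind(tab$records, tab$records[1, ])),
               "one record per")
  expect_error(add_event(tab, 0.1, "too early"), "non-decreasing")
})

test_that("overlays draw indicators on tracked frames and nothing else", {
  ph <- small_phantom(od_um = 80, n_frames = 2, frame_w = 200, frame_h = 100)
  r <- render_stack(ph$spec)
  tab <- track_stack(r$stack, ph$line)
  path <- tempfile(fileext = ".tiff")
  write_overlay(r$stack, tab, list(ph$line), path)
  ov <- read_stack(path, 1, ph$spec$calibration)
  raw <- round(r$stack$frames[[1]])
  diffmask <- which(ov$frames[[1]] != raw)
  idx <- myographr:::overlay_indices(dim(raw), list(ph$line),
                                     tab$records[tab$records$frame == 0, ])
  drawn <- union(idx$line, union(idx$outer, idx$inner))
  expect_true(all(diffmask %in% drawn))
  expect_gt(length(intersect(diffmask, idx$outer)), 0)
  # inner and outer ticks carry distinct gray levels
  expect_equal(unique(ov$frames[[1]][setdiff(idx$outer, idx$line)]), 255)
  expect_equal(unique(ov$frames[[1]][setdiff(idx$inner,
                                             union(idx$outer, idx$line))]), 64)

  # failed frames draw the line but no ticks
  noise_tab <- tab
  noise_tab$records[noise_tab$records$frame == 1,
                    c("outer_left_px", "inner_left_px",
                      "inner_right_px", "outer_right_px")] <- NA_real_
  noise_tab$records$status[noise_tab$records$frame == 1] <- "failed"
  write_overlay(r$stack, noise_tab, list(ph$line), path)
  ov2 <- read_stack(path, 1, ph$spec$calibration)
  d2 <- which(ov2$frames[[2]] != round(r$stack$frames[[2]]))
  idx2 <- myographr:::overlay_indices(dim(raw), list(ph$line),
                                      noise_tab$records[noise_tab$records$frame == 1, ])
  expect_true(all(d2 %in% idx2$line))

  # an empty table leaves the stack untouched
  empty <- result_table(tab$records[0, ])
  write_overlay(r$stack, empty, list(ph$line), path)
  ov3 <- read_stack(path, 1, ph$spec$calibration)
  for (i in 1:2) expect_equal(ov3$frames[[i]], round(r$stack$frames[[i]]))
})

test_that("session configs resolve calibrations, lines and parameters", {
  cfg_path <- tempfile(fileext = ".yml")
  writeLines(c(
    "seed: 7",
    "frame_interval: 0.5",
    "calibrations:",
    "  cmos_10x: {camera_pixel_um: 3.45, magnification: 10}",
    "  emccd_20x: {camera_pixel_um: 13, magnification: 20}",
    "calibration: cmos_10x",
    "lines:",
    "  - {id: 1, kind: roi_horizontal, x: 4, y: 4, width: 190, height: 90}",
    "  - {id: 2, kind: segment, x0: 10, y0: 10, x1: 60, y1: 80, mode: fluorescence}",
    "detection: {smooth_window: 7, k: 2.5}",
    "tracking: {k_frames: 3, max_jump_fraction: 0.4}",
    "protocol: {start: 20, stop: 100, step: 20, hold: 60}"
  ), cfg_path)
  cfg <- read_session_config(cfg_path)
  expect_equal(cfg$calibration$scale, 0.345)
  expect_equal(cfg$calibration$label, "cmos_10x")
  expect_length(cfg$lines, 2L)
  expect_equal(cfg$lines[[2]]$mode, "fluorescence")
  expect_equal(cfg$detect$smooth_window, 7L)
  expect_equal(cfg$detect$k, 2.5)
  expect_equal(cfg$track$k_frames, 3L)
  expect_equal(cfg$protocol$stop, 100)
  expect_equal(cfg$seed, 7L)
  expect_error(session_config(list(calibration = "nope",
                                   calibrations = list())),
               "not found")
})

test_that("simulate then analyze reproduces phantom ground truth end to end", {
  out <- tempfile(); dir.create(out)
  cfg <- session_config(list(
    seed = 3,
    frame_interval = 1,
    calibration = list(scale = 0.5),
    lines = list(list(id = 1, kind = "roi_horizontal", x = 4, y = 4,
                      width = 232, height = 102)),
    phantom = list(geometry = "straight", frame_size = c(240, 110),
                   od_track = c(100, 100, 95, 90, 90), noise_sd = 2)
  ))
  simulate_session(cfg, out, base = "demo")
  suppressMessages(
    tab <- analyze_session(file.path(out, "demo.tiff"), cfg, out,
                           base = "demo"))
  truth <- utils::read.csv(file.path(out, "demo_truth.csv"))
  expect_equal(nrow(tab$records), 5L)
  expect_true(all(tab$records$status == "tracked"))
  expect_lt(max(abs(tab$records$outer_um - truth$od_um)), 1)
  expect_true(file.exists(file.path(out, "demo_results.csv")))
  expect_true(file.exists(file.path(out, "demo_overlay.tiff")))

  # the whole pipeline is deterministic given the config seed
  out2 <- tempfile(); dir.create(out2)
  simulate_session(cfg, out2, base = "demo")
  suppressMessages(analyze_session(file.path(out2, "demo.tiff"), cfg, out2,
                                   base = "demo"))
  expect_identical(readLines(file.path(out, "demo_results.csv")),
                   readLines(file.path(out2, "demo_results.csv")))
})
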