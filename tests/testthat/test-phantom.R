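test_that("rendering is seeded-deterministic and guards degenerate walls", {
  ph <- small_phantom(od_um = 80, n_frames = 3, noise_sd = 4,
                      frame_w = 200, frame_h = 100)
  a <- render_stack(ph$spec)
  b <- render_stack(ph$spec)
  for (i in 1:3) expect_identical(a$stack$frames[[i]], b$stack$frames[[i]])
  # distinct frames get distinct noise
  expect_false(identical(a$stack$frames[[1]], a$stack$frames[[2]]))
  # tracking a deterministic stack twice gives identical tables
  t1 <- track_stack(a$stack, ph$line)
  t2 <- track_stack(b$stack, ph$line)
  expect_identical(t1$records, t2$records)

  spec <- phantom_spec("straight", frame_size = c(120, 80), od_track = 40,
                       id_fraction = 0.999, calibration = calibration(1))
  expect_error(render_frame(spec, 0), "degenerate")
})

test_that("tracked diameters match ground truth for every modality", {
  for (mod in c("brightfield", "fluorescence", "ultrasound")) {
    ph <- small_phantom(od_um = 100, modality = mod, frame_w = 280,
                        frame_h = 130)
    fr <- render_frame(ph$spec, 0)
    rec <- measure_line(fr$frame, ph$line, ph$spec$calibration)
    expect_lt(abs(rec$outer_um - 100) / 0.5, 0.25)  # < 0.25 px
    expect_lt(abs(rec$inner_um - 60) / 0.5, 0.25)
  }
  phs <- small_phantom(od_um = 90, modality = "en_face", frame_w = 280,
                       frame_h = 130)
  spec <- phantom_spec("strip", frame_size = c(280, 130), od_track = 90,
                       modality = "en_face", calibration = calibration(0.5))
  rec <- measure_line(render_frame(spec, 0)$frame, phs$line,
                      spec$calibration)
  expect_lt(abs(rec$outer_um - 90) / 0.5, 0.25)
  expect_true(is.na(rec$inner_um))
})

test_that("measured spread grows with rendering noise", {
  sds <- vapply(c(1, 4, 10), function(noise_sd) {
    meas <- vapply(1:40, function(i) {
      ph <- small_phantom(od_um = 80, frame_w = 200, frame_h = 90,
                          noise_sd = noise_sd, seed = 1000 * noise_sd + i)
      measure_line(render_frame(ph$spec, 0)$frame, ph$line,
                   ph$spec$calibration)$outer_um
    }, numeric(1))
    stats::sd(meas)
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("diameter dynamics follow their closed forms", {
  expect_equal(simulate_dynamics("drug_step",
                                 list(n_frames = 10, dt = 1, start_od = 150)),
               rep(150, 10))
  # single constriction event, value one time constant later
  ev <- data.frame(time = 5, target = 100)
  od <- simulate_dynamics("drug_step",
                          list(n_frames = 30, dt = 1, start_od = 150,
                               events = ev, tau_s = 10))
  expect_equal(od[1:6], rep(150, 6))  # event takes effect after t = 5
  expect_equal(od[16], 150 + (1 - exp(-1)) * (100 - 150), tolerance = 1e-9)
  expect_error(simulate_dynamics("drug_step", list(tau_s = -1)), "positive")

  P <- seq(0, 160, by = 5)
  passive <- simulate_dynamics("pressure_curve", list(pressures = P))
  active <- simulate_dynamics("pressure_curve",
                              list(pressures = P, active = TRUE))
  tone <- passive - active
  expect_true(all(tone >= 0))
  expect_true(all(tone[P <= 60] == 0))
  expect_true(all(tone[P > 60] > 0))
  expect_error(simulate_dynamics("pressure_curve", list(Pc = 0)), "positive")
})

test_that("branched phantoms measure each arm independently", {
  spec <- phantom_spec("branched3", frame_size = c(340, 340),
                       od_track = matrix(rep(c(150, 100, 80), each = 3),
                                         3, 3),
                       calibration = calibration(1))
  b <- make_branched_stack(spec)
  tab <- track_stack(b$stack, b$lines)
  for (arm in 1:3) {
    got <- tab$records$outer_um[tab$records$line_id == arm]
    expect_lt(max(abs(got - c(150, 100, 80)[arm])), 0.5)
  }

  # identical diameter tracks give identical traces arm to arm
  spec_sym <- phantom_spec("branched3", frame_size = c(300, 300),
                           od_track = matrix(90, 2, 3),
                           arm_angles = c(90, 210, 330),
                           calibration = calibration(1))
  bs <- make_branched_stack(spec_sym)
  ts <- track_stack(bs$stack, bs$lines)
  ods <- tapply(ts$records$outer_um, ts$records$line_id, mean)
  expect_lt(diff(range(ods)), 0.5)

  # ramping one arm leaves the other traces untouched
  tr <- matrix(100, 6, 3)
  tr[, 2] <- seq(100, 130, length.out = 6)
  spec_r <- phantom_spec("branched3", frame_size = c(340, 340),
                         od_track = tr, calibration = calibration(1))
  br <- make_branched_stack(spec_r)
  tbr <- track_stack(br$stack, br$lines)
  for (arm in c(1, 3)) {
    expect_lt(diff(range(tbr$records$outer_um[tbr$records$line_id == arm])),
              0.25)
  }
  ramped <- tbr$records$outer_um[tbr$records$line_id == 2]
  expect_lt(max(abs(ramped - tr[, 2])), 0.5)

  # arms crowding a measurement region raise a geometry error
  spec_bad <- phantom_spec("branched3", frame_size = c(300, 300),
                           od_track = matrix(c(160, 160, 60), 1, 3),
                           arm_angles = c(80, 110, 270),
                           calibration = calibration(1))
  expect_error(make_branched_stack(spec_bad), "geometry error")
})
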