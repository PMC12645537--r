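# Independent brute-force peak enumerator: direct scan over every sample,
# explicit plateau handling, prominence by whole-signal scans. Used as the
# oracle for detect_peaks.
brute_peaks <- function(v, min_prominence = 0, min_separation = 1) {
  n <- length(v)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j < n && v[i] > v[i - 1L] && v[i] > v[j + 1L]) cand <- c(cand, i)
    i <- j + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- v[i]
    higher_l <- which(v[seq_len(i - 1L)] > h)
    from <- if (length(higher_l)) max(higher_l) + 1L else 1L
    left_min <- min(v[from:(i - 1L)])
    higher_r <- which(v[(i + 1L):n] > h)
    to <- if (length(higher_r)) i + min(higher_r) - 1L else n
    right_min <- min(v[(i + 1L):to])
    h - max(left_min, right_min)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) <= 1L || min_separation <= 1) return(cand)
  kept <- integer(0)
  for (i in cand[order(-v[cand], cand)]) {
    if (!length(kept) || min(abs(kept - i)) >= min_separation) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

# The standard brightfield test profile: bright background, dark walls,
# grey lumen, with transitions at analytic midpoints 39.5 / 51.5 / 111.5 /
# 123.5 (0-based positions).
std_bf_profile <- function() {
  c(rep(200, 40), rep(50, 12), rep(150, 60), rep(50, 12), rep(200, 40))
}

# Piecewise brightfield vessel profile on a canvas, with the vessel placed
# at `center` (0-based) and transitions softened by a narrow moving average
# emulating a PSF. Returns the analytic outer/inner edge positions.
synth_bf_profile <- function(n = 180, center = NULL, od = 90, idf = 0.6,
                             bg = 200, wall = 50, lumen = 150,
                             noise_sd = 0, seed = NULL) {
  if (is.null(center)) center <- (n - 1) / 2
  x <- 0:(n - 1)
  a <- od / 2
  b <- od * idf / 2
  v <- rep(bg, n)
  v[abs(x - center) <= a] <- wall
  v[abs(x - center) <= b] <- lumen
  v <- as.numeric(stats::filter(c(rep(v[1], 2), v, rep(v[n], 2)),
                                rep(1 / 3, 3), sides = 2))[3:(n + 2)]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(n, 0, noise_sd)
  }
  # transitions sit midway between the last sample of one level and the
  # first of the next, so the analytic edges depend on the sample grid
  list(values = v,
       outer = c(ceiling(center - a) - 0.5, floor(center + a) + 0.5),
       inner = c(ceiling(center - b) - 0.5, floor(center + b) + 0.5))
}

# Two-Gaussian-band fluorescence profile; bands centred at `c1`, `c2`.
gauss_band_profile <- function(n = 160, c1 = 30, c2 = 130, sigma = 4,
                               amp = 100, offset = 0) {
  x <- 0:(n - 1)
  amp * exp(-(x - c1)^2 / (2 * sigma^2)) +
    amp * exp(-(x - c2)^2 / (2 * sigma^2)) + offset
}

# A small straight-vessel phantom plus a horizontal ROI spanning it.
small_phantom <- function(od_um = 100, modality = "brightfield",
                          scale = 0.5, frame_w = 300, frame_h = 160,
                          n_frames = 1, noise_sd = 0, seed = 1,
                          psf_sigma = 0.8, id_fraction = 0.6) {
  spec <- phantom_spec("straight", frame_size = c(frame_w, frame_h),
                       od_track = rep(od_um, n_frames),
                       id_fraction = id_fraction, modality = modality,
                       psf_sigma = psf_sigma, noise_sd = noise_sd,
                       calibration = calibration(scale), seed = seed)
  line <- track_line(1L, "roi_horizontal", x = 4, y = 4,
                     width = frame_w - 8, height = frame_h - 8,
                     mode = modality)
  list(spec = spec, line = line)
}
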