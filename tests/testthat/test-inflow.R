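make_stack <- function(frames_fun, n, h = 16L, w = 16L, fr = 2) {
  arr <- array(0, c(h, w, n))
  for (i in seq_len(n)) arr[, , i] <- frames_fun(i)
  frame_stack(arr, fr)
}

test_that("ROI series extraction equals the brute-force pixel scan", {
  st <- make_stack(function(i) matrix(10, 16, 16), 5)
  roi <- circular_roi(8, 8, 3)
  expect_equal(extract_roi_series(st, roi), rep(10, 5))

  st2 <- make_stack(function(i) matrix(i - 1, 16, 16), 6)
  expect_equal(extract_roi_series(st2, roi), 0:5)

  set.seed(71)
  st3 <- make_stack(function(i) matrix(runif(256, 0, 255), 16, 16), 4)
  got <- extract_roi_series(st3, roi)
  for (i in 1:4) expect_equal(got[i], o_disc_mean(st3$frames[, , i], 8, 8, 3))

  expect_error(extract_roi_series(st, circular_roi(15, 8, 3)),
               class = "icgperf_validation_error")
})

test_that("laser template matching recovers levels and flags unreadable frames", {
  bank <- laser_template_bank()
  frame <- matrix(0, 20, 20)
  ind <- list(x = 9, y = 3, w = 8, h = 12)
  frame[3:14, 9:16] <- render_laser_template(0.5)
  expect_equal(estimate_laser_intensity(frame, ind, bank), 0.5)

  # mild Gaussian noise on the full-power template still matches level 1.0,
  # in agreement with oracle NCC scoring
  set.seed(72)
  noisy <- render_laser_template(1.0) + matrix(rnorm(96, sd = 2), 12, 8)
  frame[3:14, 9:16] <- noisy
  o_scores <- sapply(bank$templates, function(tm) {
    a <- as.vector(noisy) - mean(noisy); b <- as.vector(tm) - mean(tm)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  expect_equal(bank$levels[which.max(o_scores)], 1.0)
  expect_equal(estimate_laser_intensity(frame, ind, bank), 1.0)

  frame[3:14, 9:16] <- 30  # blank indicator
  expect_error(estimate_laser_intensity(frame, ind, bank),
               class = "icgperf_unreadable_indicator")
})

test_that("curve building normalises by laser and smooths with movmean", {
  # laser constant 1: normalized equals raw
  st <- make_stack(function(i) matrix(3 * i, 16, 16), 8)
  cv <- build_curve(st, circular_roi(8, 8, 3), indicator = NULL, window_s = 1.5)
  expect_equal(cv$normalized, cv$raw)

  # constant raw 100 with laser 0.5 doubles; smoothing keeps constants
  bank <- laser_template_bank()
  st2 <- make_stack(function(i) {
    f <- matrix(100, 20, 20)
    f[1:12, 13:20] <- render_laser_template(0.5)
    f
  }, 10, h = 20L, w = 20L)
  roi <- circular_roi(7, 14, 3)
  cv2 <- build_curve(st2, roi, list(x = 13, y = 1, w = 8, h = 12), bank, window_s = 3)
  expect_equal(cv2$laser, rep(0.5, 10))
  roi_mean <- extract_roi_series(st2, roi)
  expect_equal(cv2$normalized, roi_mean / 0.5)
  expect_equal(cv2$smoothed, cv2$normalized)  # constant under smoothing

  # ramp with a known laser dip: hand-computed normalisation and movmean
  raw <- seq(0, 90, by = 10)
  laser <- c(1, 1, 1, 0.5, 0.5, 1, 1, 1, 1, 1)
  cv3 <- inflow_curve(t_s = 0:9, raw = raw, laser = laser, window_frames = 3)
  expect_equal(cv3$normalized, raw / laser)
  expect_equal(cv3$smoothed, o_movmean(raw / laser, 3))
})

test_that("movmean shrinks symmetrically at the ends and preserves constants", {
  set.seed(73)
  x <- rnorm(30)
  for (k in c(1, 3, 5, 8)) expect_equal(movmean(x, k), o_movmean(x, k))
  expect_equal(movmean(rep(2.5, 10), 7), rep(2.5, 10))
})

test_that("background noise is the smoothed maximum over the 3-6 s window", {
  cv <- inflow_curve(t_s = seq(0, 10, by = 0.5), raw = rep(0, 21))
  expect_equal(background_noise(cv), 0)

  raw <- rep(5, 21); raw[9] <- 8  # spike at t = 4 s
  cv2 <- inflow_curve(t_s = seq(0, 10, by = 0.5), raw = raw, window_frames = 1)
  expect_equal(background_noise(cv2), 8)

  set.seed(74)
  raw3 <- runif(41, 0, 10)
  cv3 <- inflow_curve(t_s = seq(0, 20, by = 0.5), raw = raw3, window_frames = 5)
  inw <- cv3$t_s >= 3 & cv3$t_s <= 6
  expect_equal(background_noise(cv3), max(cv3$smoothed[inw]))

  short <- inflow_curve(t_s = seq(4, 10, by = 0.5), raw = rep(0, 13))
  expect_error(background_noise(short), class = "icgperf_range_error")
})

test_that("objective T0 is the start of the permanently-above-background phase", {
  t <- seq(0, 40, by = 0.5)
  step <- ifelse(t >= 20, 100, 0)
  cv <- inflow_curve(t, step, window_frames = 1)
  expect_equal(t0_objective(cv, B = 0), 20)

  # crosses at 15 s, dips below once at 18 s, above forever after 19 s
  t1 <- 0:40
  y <- ifelse(t1 >= 15, 50, 0); y[t1 == 18] <- -1
  cv2 <- inflow_curve(t1, y, window_frames = 1)
  expect_equal(t0_objective(cv2, B = 0), 19)

  # never rises
  cv3 <- inflow_curve(t, rep(0, length(t)), window_frames = 1)
  expect_error(t0_objective(cv3, B = 0), class = "icgperf_no_inflow")

  # definition-scan oracle agreement on noisy sigmoids
  set.seed(75)
  for (i in 1:20) {
    t0t <- runif(1, 10, 30)
    y <- 100 / (1 + exp(-1.5 * (t - t0t - 4))) + rnorm(length(t), sd = 2)
    cv4 <- inflow_curve(t, y, window_frames = 7)
    B <- background_noise(cv4)
    expect_equal(t0_objective(cv4, B), o_t0_scan(cv4, B))
  }
})

test_that("inflow slope fits the steepest-run segment by OLS", {
  t <- seq(0, 30, by = 0.5)
  cv <- inflow_curve(t, 2 * t, window_frames = 5)  # pure line
  expect_equal(inflow_slope(cv), 2, tolerance = 1e-12)

  cv2 <- inflow_curve(t, rep(7, length(t)), window_frames = 5)
  expect_error(inflow_slope(cv2), class = "icgperf_no_inflow")

  # logistic inflow: matches the independent segment-rule implementation
  # and sits within 15% of the analytic maximum slope L*k/4
  L <- 200; k <- 0.8; ctr <- 15
  set.seed(76)
  for (noise in c(0, 1)) {
    y <- L / (1 + exp(-k * (t - ctr))) + rnorm(length(t), sd = noise)
    cv3 <- inflow_curve(t, y, window_frames = 3)
    got <- inflow_slope(cv3)
    expect_equal(got, o_slope_rule(cv3), tolerance = 1e-9)
    expect_lt(abs(got - L * k / 4) / (L * k / 4), 0.15)
  }
})

test_that("time to peak finds the laser plateau onset after the first drop", {
  t <- seq(0, 30, by = 0.5)
  las <- ifelse(t < 12, 1 - 0.03 * t, 1 - 0.03 * 12)
  expect_equal(time_to_peak(las, t_s = t), 12)

  expect_true(is.na(time_to_peak(1 - 0.01 * t, t_s = t)))

  set.seed(77)
  las2 <- c(seq(1, 0.6, length.out = 30), 0.6 + abs(rnorm(31, sd = 0.005)))
  expect_equal(time_to_peak(las2, t_s = t), o_ttp_scan(las2, t))
})

test_that("literature threshold flags use strict comparisons", {
  f <- classify_thresholds(t0_s = 20.3, slope_units_per_s = 119.5)
  expect_false(f$wada_slope_lt_2.1)
  expect_false(f$hayami_t0_gt_60)
  expect_false(f$kim_t0_gt_40)

  f2 <- classify_thresholds(65, 50)
  expect_true(f2$hayami_t0_gt_60)
  expect_true(f2$kim_t0_gt_40)

  expect_false(classify_thresholds(20, 2.1)$wada_slope_lt_2.1)  # boundary
  expect_true(classify_thresholds(20, 2.0999)$wada_slope_lt_2.1)
})

test_that("T0 and ttp are time-shift equivariant; slope scales with intensity", {
  t <- seq(0, 40, by = 0.5)
  set.seed(78)
  y <- 150 / (1 + exp(-(t - 22))) + rnorm(length(t), sd = 1.5)
  cv <- inflow_curve(t, y, window_frames = 5)
  B <- background_noise(cv)
  t0 <- t0_objective(cv, B)

  delta <- 4
  cvs <- inflow_curve(t + delta, y, window_frames = 5)
  Bs <- background_noise(cvs, noise_window_s = c(3, 6) + delta)
  expect_equal(Bs, B)
  expect_equal(t0_objective(cvs, Bs, search_from_s = 6 + delta,
                            noise_window_s = c(3, 6) + delta), t0 + delta)

  c_scale <- 3.2
  cvc <- inflow_curve(t, y * c_scale, window_frames = 5)
  expect_equal(background_noise(cvc), B * c_scale)
  expect_equal(t0_objective(cvc, B * c_scale), t0)
  expect_equal(inflow_slope(cvc), inflow_slope(cv) * c_scale, tolerance = 1e-12)
})

test_that("frame stacks round-trip through TIFF and PNG layouts", {
  set.seed(79)
  st <- frame_stack(array(runif(16 * 16 * 4, 0, 255), c(16, 16, 4)), 5)
  dir <- withr::local_tempdir()

  tif <- file.path(dir, "stack.tiff")
  write_frame_stack(st, tif)
  back <- read_frame_stack(tif)
  expect_equal(back$frames, st$frames, tolerance = 1e-4)  # float32
  expect_equal(back$frame_rate_hz, 5)

  pngdir <- file.path(dir, "frames")
  write_frame_stack(st, pngdir)
  back2 <- read_frame_stack(pngdir)
  expect_equal(back2$frames, st$frames, tolerance = 255 / 2^8)  # 8-bit quantised
})
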