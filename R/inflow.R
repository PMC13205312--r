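# Quantitative ICG fluorescence inflow analysis. Video capture starts with
# the intravenous ICG bolus; per-ROI mean intensities are normalised to the
# excitation laser level (read off an on-screen indicator by template
# matching), smoothed with a 3-s moving average, and summarised by the
# background-noise maximum B (3-6 s window), the objective time to first
# fluorescence T0, the inflow slope over the steepest segment, and the
# laser-plateau time to peak.

#' ICG video frame stack
#'
#' @param frames numeric array `(rows, cols, n_frames)` of grayscale
#'   intensities on the 0-255 scale; at least 2 frames.
#' @param frame_rate_hz frames per second (> 0); frames are assumed
#'   uniformly spaced.
#' @param t0_admin_s time of ICG administration on the stack clock
#'   (default 0: capture starts with the bolus).
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_rate_hz, t0_admin_s = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    validation_error("frames must be a 3-d array (rows, cols, frames)")
  if (dim(frames)[3] < 2L) validation_error("a frame stack needs at least 2 frames")
  if (!is_scalar_number(frame_rate_hz) || frame_rate_hz <= 0)
    validation_error("frame_rate_hz must be a positive scalar")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 t0_admin_s = t0_admin_s),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %.1f Hz (%.1f s)\n",
              d[3], d[1], d[2], x$frame_rate_hz, d[3] / x$frame_rate_hz))
  invisible(x)
}

frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[3]) - 1L) / stack$frame_rate_hz - stack$t0_admin_s
}

#' Mean ROI intensity per frame
#'
#' @param stack a [frame_stack()].
#' @param roi a [circular_roi()] fully inside the frame bounds.
#' @return numeric vector: per-frame arithmetic mean over the ROI disc.
#' @export
extract_roi_series <- function(stack, roi) {
  d <- dim(stack$frames)
  roi_check_inside(roi, d[1], d[2], "frame")
  idx <- disc_indices(roi$x, roi$y, roi$r, d[1], d[2])
  m <- matrix(stack$frames, d[1] * d[2], d[3])
  colMeans(m[idx, , drop = FALSE])
}

# ---- laser intensity indicator ---------------------------------------------

#' Render a laser-intensity indicator template
#'
#' Deterministic synthetic rendering of the on-screen laser-level
#' indicator: a vertical fill bar (filled rows proportional to `level`)
#' with a fixed tick texture, on the 0-255 intensity scale. The real
#' device's indicator glyph is not standardised; this bank abstracts it for
#' template matching and for the synthetic video generator.
#'
#' @param level laser level in `(0, 1]`.
#' @param height,width template size in pixels.
#' @return numeric matrix `height x width`.
#' @export
render_laser_template <- function(level, height = 12L, width = 8L) {
  if (!is_scalar_number(level) || level <= 0 || level > 1)
    validation_error("laser level must be in (0, 1]")
  img <- matrix(20, height, width)
  img[seq(1L, height, by = 2L), 1L] <- 60  # tick column
  nfill <- max(1L, round(level * height))
  img[(height - nfill + 1L):height, 2:width] <- 230
  img
}

#' Laser template bank
#'
#' @param levels laser levels in `(0, 1]`, default `0.1, 0.2, ..., 1.0`.
#' @param height,width template size in pixels.
#' @return object of class `laser_template_bank`: list with `levels` and
#'   `templates` (list of matrices).
#' @export
laser_template_bank <- function(levels = seq(0.1, 1, by = 0.1),
                                height = 12L, width = 8L) {
  if (length(levels) == 0L) validation_error("template bank must be non-empty")
  structure(list(levels = as.numeric(levels),
                 templates = lapply(levels, render_laser_template,
                                    height = height, width = width)),
            class = "laser_template_bank")
}

# normalized cross-correlation scores: rows of `crops` vs rows of `templ`
ncc_scores <- function(crops, templ) {
  cc <- crops - rowMeans(crops)
  tc <- templ - rowMeans(templ)
  cn <- sqrt(rowSums(cc^2))
  tn <- sqrt(rowSums(tc^2))
  s <- (cc %*% t(tc)) / (pmax(cn, 1e-300) %o% pmax(tn, 1e-300))
  s[cn == 0, ] <- 0
  s
}

crop_region <- function(frame, indicator) {
  x <- indicator$x; y <- indicator$y; w <- indicator$w; h <- indicator$h
  if (x < 1 || y < 1 || x + w - 1 > ncol(frame) || y + h - 1 > nrow(frame))
    validation_error("indicator region outside frame bounds")
  frame[y:(y + h - 1L), x:(x + w - 1L), drop = FALSE]
}

#' Estimate the laser level of one frame by template matching
#'
#' Crops the indicator region, scores it against every template in the
#' bank by normalized cross-correlation, and returns the level of the
#' best-scoring template (ties broken toward the higher level). If no
#' template scores above `floor` the indicator is unreadable and an error
#' of class `icgperf_unreadable_indicator` is signalled; callers working on
#' whole stacks interpolate such frames from readable neighbours.
#'
#' @param frame grayscale matrix (0-255).
#' @param indicator list `(x, y, w, h)`: 1-based top-left corner and size
#'   of the indicator region.
#' @param bank a [laser_template_bank()].
#' @param floor minimum acceptable correlation score.
#' @return laser level in `(0, 1]`.
#' @export
estimate_laser_intensity <- function(frame, indicator, bank, floor = 0.2) {
  crop <- crop_region(frame, indicator)
  td <- dim(bank$templates[[1]])
  if (!all(dim(crop) == td))
    validation_error(sprintf("indicator region %d x %d does not match template size %d x %d",
                             nrow(crop), ncol(crop), td[1], td[2]))
  tm <- t(vapply(bank$templates, as.vector, numeric(prod(td))))
  s <- ncc_scores(matrix(as.vector(crop), 1L), tm)[1L, ]
  if (max(s) < floor)
    abort("laser indicator unreadable (all template scores below floor)",
          "icgperf_unreadable_indicator")
  best <- which(s >= max(s) - 1e-12)
  max(bank$levels[best])
}

# per-frame laser series with linear interpolation over unreadable frames
estimate_laser_series <- function(stack, indicator, bank, floor = 0.2) {
  d <- dim(stack$frames)
  n <- d[3]
  td <- dim(bank$templates[[1]])
  crop1 <- crop_region(stack$frames[, , 1L], indicator)
  if (!all(dim(crop1) == td))
    validation_error("indicator region size does not match template size")
  npix <- prod(td)
  crops <- matrix(0, n, npix)
  for (i in seq_len(n))
    crops[i, ] <- as.vector(crop_region(stack$frames[, , i], indicator))
  tm <- t(vapply(bank$templates, as.vector, numeric(npix)))
  s <- ncc_scores(crops, tm)
  best_score <- apply(s, 1L, max)
  lvl <- vapply(seq_len(n), function(i) {
    best <- which(s[i, ] >= best_score[i] - 1e-12)
    max(bank$levels[best])
  }, 0)
  lvl[best_score < floor] <- NA_real_
  if (all(is.na(lvl)))
    abort("laser indicator unreadable in every frame", "icgperf_unreadable_indicator")
  if (anyNA(lvl)) {
    ok <- which(!is.na(lvl))
    lvl <- stats::approx(ok, lvl[ok], xout = seq_len(n), rule = 2)$y
  }
  lvl
}

# ---- inflow curve -----------------------------------------------------------

#' Build a laser-normalised, smoothed inflow curve
#'
#' Extracts the per-frame ROI mean, estimates the per-frame laser level by
#' template matching (unreadable frames interpolated), normalises
#' `raw / laser`, and smooths with a centred moving average of
#' `round(window_s * frame_rate)` frames (forced odd by adding one), with
#' symmetrically shrinking windows at the curve ends.
#'
#' @param stack a [frame_stack()].
#' @param roi a [circular_roi()].
#' @param indicator indicator region `list(x, y, w, h)`; `NULL` for a
#'   constant laser level of 1 (no indicator in the video).
#' @param bank a [laser_template_bank()]; ignored when `indicator` is NULL.
#' @param window_s moving-average window in seconds (> 0), default 3.
#' @return object of class `inflow_curve` with `t_s`, `raw`, `laser`,
#'   `normalized`, `smoothed`.
#' @export
build_curve <- function(stack, roi, indicator = NULL,
                        bank = laser_template_bank(), window_s = 3) {
  if (!is_scalar_number(window_s) || window_s <= 0)
    validation_error("window_s must be a positive scalar")
  raw <- extract_roi_series(stack, roi)
  laser <- if (is.null(indicator)) rep(1, length(raw))
           else estimate_laser_series(stack, indicator, bank)
  if (any(laser <= 0)) validation_error("laser levels must be positive")
  normalized <- raw / laser
  k <- as.integer(round(window_s * stack$frame_rate_hz))
  if (k < 1L) k <- 1L
  if (k %% 2L == 0L) k <- k + 1L
  structure(list(t_s = frame_times(stack), raw = raw, laser = laser,
                 normalized = normalized, smoothed = movmean(normalized, k),
                 window_frames = k),
            class = "inflow_curve")
}

#' Inflow curve from precomputed series
#'
#' Convenience constructor for analyses that already have the time base and
#' intensity series (e.g. exported curves), bypassing video extraction.
#'
#' @param t_s times since administration (strictly increasing).
#' @param raw raw ROI mean intensities.
#' @param laser per-sample laser levels in `(0, 1]`; default constant 1.
#' @param window_frames odd moving-average length in samples, default 1
#'   frame per second equivalent handled by the caller.
#' @return an `inflow_curve`.
#' @export
inflow_curve <- function(t_s, raw, laser = rep(1, length(raw)), window_frames = 1L) {
  if (length(t_s) != length(raw) || length(raw) != length(laser))
    validation_error("t_s, raw and laser must have equal length")
  if (any(diff(t_s) <= 0)) validation_error("t_s must be strictly increasing")
  if (any(laser <= 0)) validation_error("laser levels must be positive")
  k <- as.integer(window_frames)
  if (k %% 2L == 0L) k <- k + 1L
  normalized <- raw / laser
  structure(list(t_s = as.numeric(t_s), raw = as.numeric(raw),
                 laser = as.numeric(laser), normalized = normalized,
                 smoothed = movmean(normalized, k), window_frames = k),
            class = "inflow_curve")
}

#' Maximum background noise B
#'
#' The maximum of the smoothed, laser-normalised curve over the closed
#' window `noise_window_s` seconds after administration (3-6 s by default:
#' circulation has not yet delivered ICG to the field, so this samples pure
#' background).
#'
#' @param curve an `inflow_curve`.
#' @param noise_window_s closed `[lo, hi]` window in seconds.
#' @return scalar B in normalised intensity units.
#' @export
background_noise <- function(curve, noise_window_s = c(3, 6)) {
  t <- curve$t_s
  if (min(t) > noise_window_s[1] || max(t) < noise_window_s[2])
    range_error(sprintf("curve [%.1f, %.1f] s does not cover the noise window [%.1f, %.1f] s",
                        min(t), max(t), noise_window_s[1], noise_window_s[2]))
  inw <- t >= noise_window_s[1] & t <= noise_window_s[2]
  max(curve$smoothed[inw])
}

#' Objective time to first fluorescence T0
#'
#' The smallest sample time `t*` at or after the end of the noise window
#' such that the smoothed curve exceeds `B` at every sample `t >= t*`
#' ("always higher than the background noise"), additionally requiring
#' that the normalised (unsmoothed) intensity at `t*` itself exceeds the
#' raw background maximum over the noise window: the centred moving
#' average otherwise pre-dates the onset by up to half a smoothing window,
#' since it spreads signal backwards in time. Signals an error of class
#' `icgperf_no_inflow` if the curve never stays above B.
#'
#' @param curve an `inflow_curve`.
#' @param B background noise maximum from [background_noise()].
#' @param search_from_s start of the search (default 6 s: end of the noise
#'   window).
#' @param noise_window_s window used for the raw confirmation threshold;
#'   must match the window `B` was computed on.
#' @return T0 in seconds.
#' @export
t0_objective <- function(curve, B, search_from_s = 6, noise_window_s = c(3, 6)) {
  t <- curve$t_s
  n <- length(t)
  i0 <- which(t >= search_from_s)[1]
  if (is.na(i0)) range_error("curve does not extend past the noise window")
  ok <- curve$smoothed > B
  if (!ok[n])
    abort("no inflow detected: curve does not end above the background noise",
          "icgperf_no_inflow")
  viol <- which(!ok[i0:n]) + i0 - 1L
  cand <- if (length(viol) == 0L) i0 else max(viol) + 1L
  if (cand > n) abort("no inflow detected", "icgperf_no_inflow")
  inw <- t >= noise_window_s[1] & t <= noise_window_s[2]
  B_raw <- if (any(inw)) max(B, curve$normalized[inw]) else B
  conf <- which(curve$normalized[cand:n] > B_raw)
  if (length(conf) == 0L)
    abort("no inflow detected: intensity never exceeds the background noise",
          "icgperf_no_inflow")
  t[cand + conf[1] - 1L]
}

#' Inflow slope over the steepest curve segment
#'
#' Local slopes are central differences of the smoothed curve; the fitting
#' segment is the maximal contiguous run, containing the global maximum
#' local slope, where the local slope is at least `fraction` of that
#' maximum. The slope is the ordinary least-squares coefficient of the
#' smoothed values against time over that segment, in normalised intensity
#' units per second.
#'
#' The run boundaries carry the smoothing transients of the moving
#' average (samples whose window straddles the run edge), so the fit
#' segment is trimmed by half the smoothing window at each end whenever
#' enough samples remain; on a noiseless linear rise this makes the OLS
#' estimate exact.
#'
#' @param curve an `inflow_curve` with at least 5 samples.
#' @param fraction run-membership threshold as a fraction of the maximum
#'   local slope (default 0.5).
#' @return slope in units per second.
#' @export
inflow_slope <- function(curve, fraction = 0.5) {
  s <- curve$smoothed
  t <- curve$t_s
  n <- length(s)
  if (n < 5L) validation_error("inflow slope needs at least 5 samples")
  ki <- 2:(n - 1L)
  ds <- (s[ki + 1L] - s[ki - 1L]) / (t[ki + 1L] - t[ki - 1L])
  mx <- max(ds)
  if (mx <= 0)
    abort("no inflow detected: maximum local slope is not positive",
          "icgperf_no_inflow")
  im <- which.max(ds)
  keep <- ds >= fraction * mx
  L <- im; while (L > 1L && keep[L - 1L]) L <- L - 1L
  R <- im; while (R < length(ds) && keep[R + 1L]) R <- R + 1L
  seg <- (L + 1L):(R + 1L)  # interior index -> sample index
  w <- if (is.null(curve$window_frames)) 1L else curve$window_frames
  trim <- as.integer(ceiling(w / 2))
  if (length(seg) - 2L * trim >= max(5L, 2L))
    seg <- seg[(trim + 1L):(length(seg) - trim)]
  if (length(seg) < 3L)  # degenerate one-sample run: widen around the argmax
    seg <- max(1L, im):min(n, im + 2L)
  tt <- t[seg]; ss <- s[seg]
  sum((tt - mean(tt)) * (ss - mean(ss))) / sum((tt - mean(tt))^2)
}

#' Time to peak from the laser-intensity series
#'
#' The investigator's intraoperative rule for timing the intra-cube: once
#' the excitation laser level stops dropping any further for more than
#' `hold_s` seconds, maximum ICG fluorescence is presumed. Returns the
#' earliest time `t`, at or after the first observed drop of the laser
#' level, such that `laser(t') >= laser(t) - 1e-9` for all `t'` in
#' `[t, t + hold_s]`, or `NA` if the series never stabilises. A series
#' that never drops returns its start time (nothing to wait for).
#'
#' @param laser per-frame laser levels.
#' @param frame_rate_hz frame rate of the series.
#' @param hold_s plateau hold time in seconds (default 1).
#' @param t_s optional explicit time base (overrides `frame_rate_hz`).
#' @return onset time in seconds, or `NA_real_`.
#' @export
time_to_peak <- function(laser, frame_rate_hz = NULL, hold_s = 1, t_s = NULL) {
  n <- length(laser)
  if (is.null(t_s)) {
    if (is.null(frame_rate_hz)) validation_error("supply frame_rate_hz or t_s")
    t_s <- (seq_len(n) - 1L) / frame_rate_hz
  }
  if (t_s[n] - t_s[1] < hold_s)
    validation_error("series shorter than the hold time")
  drops <- which(diff(laser) < -1e-9)
  start <- if (length(drops) == 0L) 1L else drops[1] + 1L
  for (i in start:n) {
    jmax <- t_s[i] + hold_s
    if (jmax > t_s[n]) break
    win <- which(t_s >= t_s[i] & t_s <= jmax)
    if (all(laser[win] >= laser[i] - 1e-9)) return(t_s[i])
  }
  NA_real_
}

#' Literature-threshold flags for inflow metrics
#'
#' Published ICG-FA thresholds associated with anastomotic leakage risk:
#' slope below 2.1 units/s (Wada), T0 above 60 s (Hayami), T0 above 40 s
#' (Kim). Comparisons are strict.
#'
#' @param t0_s objective T0 in seconds.
#' @param slope_units_per_s inflow slope.
#' @param thresholds overridable list
#'   `(wada_slope = 2.1, hayami_t0 = 60, kim_t0 = 40)`.
#' @return named logical list `(wada_slope_lt_2.1, hayami_t0_gt_60,
#'   kim_t0_gt_40)` (names follow the default thresholds even when
#'   overridden).
#' @export
classify_thresholds <- function(t0_s, slope_units_per_s,
                                thresholds = list(wada_slope = 2.1,
                                                  hayami_t0 = 60, kim_t0 = 40)) {
  list(
    wada_slope_lt_2.1 = slope_units_per_s < thresholds$wada_slope,
    hayami_t0_gt_60 = t0_s > thresholds$hayami_t0,
    kim_t0_gt_40 = t0_s > thresholds$kim_t0
  )
}

#' All inflow metrics for one curve
#'
#' @param curve an `inflow_curve`.
#' @param fraction slope-segment threshold, see [inflow_slope()].
#' @param thresholds see [classify_thresholds()].
#' @return object of class `inflow_metrics`: `background_noise_B`,
#'   `t0_objective_s`, `slope_units_per_s`, `ttp_s` (laser plateau onset,
#'   may be `NA`), `threshold_flags`.
#' @export
inflow_metrics <- function(curve, fraction = 0.5,
                           thresholds = list(wada_slope = 2.1,
                                             hayami_t0 = 60, kim_t0 = 40)) {
  B <- background_noise(curve)
  t0 <- t0_objective(curve, B)
  slope <- inflow_slope(curve, fraction)
  ttp <- time_to_peak(curve$laser, t_s = curve$t_s, hold_s = 1)
  structure(list(background_noise_B = B, t0_objective_s = t0,
                 slope_units_per_s = slope, ttp_s = ttp,
                 threshold_flags = classify_thresholds(t0, slope, thresholds)),
            class = "inflow_metrics")
}

#' @export
print.inflow_metrics <- function(x, ...) {
  cat(sprintf("<inflow_metrics> B = %.2f, T0 = %.2f s, slope = %.2f units/s, ttp = %s s\n",
              x$background_noise_B, x$t0_objective_s, x$slope_units_per_s,
              ifelse(is.na(x$ttp_s), "NA", sprintf("%.2f", x$ttp_s))))
  invisible(x)
}

# ---- frame stack I/O --------------------------------------------------------

#' Write a frame stack
#'
#' Either a directory of numbered 8-bit grayscale PNG frames plus a
#' `meta.yaml` sidecar, or a single multi-page 32-bit float TIFF with a
#' `.yaml` sidecar of the same basename. TIFF pages are stored affinely
#' rescaled to `[0, 1]` (the transform is recorded in the sidecar and
#' inverted on read), since TIFF storage outside that range is undefined;
#' PNG output quantises to the camera's native 8-bit scale.
#'
#' @param stack a [frame_stack()].
#' @param path output directory, or a `.tif`/`.tiff` file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  meta <- list(frame_rate_hz = stack$frame_rate_hz, t0_admin_s = stack$t0_admin_s)
  n <- dim(stack$frames)[3]
  if (grepl("\\.tiff?$", path)) {
    vmin <- min(stack$frames)
    span <- max(max(stack$frames) - vmin, 1e-12)
    meta$value_offset <- vmin
    meta$value_scale <- span
    pages <- lapply(seq_len(n), function(i) (stack$frames[, , i] - vmin) / span)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    yaml::write_yaml(meta, sub("\\.tiff?$", ".yaml", path))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      img <- clip(stack$frames[, , i], 0, 255) / 255
      png::writePNG(img, file.path(path, sprintf("frame_%05d.png", i)))
    }
    yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  }
  invisible(path)
}

#' Read a frame stack
#'
#' Accepts the two layouts written by [write_frame_stack()].
#'
#' @param path frame directory or multi-page TIFF path.
#' @return a [frame_stack()].
#' @export
read_frame_stack <- function(path) {
  if (dir.exists(path)) {
    meta_path <- file.path(path, "meta.yaml")
    if (!file.exists(meta_path)) format_error(sprintf("'%s' has no meta.yaml", path))
    meta <- yaml::read_yaml(meta_path)
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$", full.names = TRUE))
    if (length(files) < 2L) format_error(sprintf("'%s' holds fewer than 2 frames", path))
    pages <- lapply(files, function(f) {
      if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    })
  } else if (grepl("\\.tiff?$", path) && file.exists(path)) {
    meta_path <- sub("\\.tiff?$", ".yaml", path)
    if (!file.exists(meta_path)) format_error(sprintf("sidecar '%s' not found", meta_path))
    meta <- yaml::read_yaml(meta_path)
    pages <- tiff::readTIFF(path, all = TRUE)
  } else {
    format_error(sprintf("frame stack '%s' not found", path))
  }
  if (is.null(meta$frame_rate_hz)) format_error("frame stack metadata missing frame_rate_hz")
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  d1 <- dim(pages[[1]])
  arr <- array(0, c(d1[1], d1[2], length(pages)))
  rescale <- !is.null(meta$value_scale)
  for (i in seq_along(pages)) {
    if (!all(dim(pages[[i]]) == d1)) shape_error("frames differ in shape")
    arr[, , i] <- if (rescale) pages[[i]] * meta$value_scale + meta$value_offset
                  else pages[[i]] * 255
  }
  frame_stack(arr, meta$frame_rate_hz,
              if (is.null(meta$t0_admin_s)) 0 else meta$t0_admin_s)
}
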