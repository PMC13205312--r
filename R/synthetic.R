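# Seeded synthetic-data generators with attached ground truth. They emulate
# the intraoperative acquisitions: hyperspectral reflectance cubes with a
# proximal-to-distal perfusion gradient and an ICG absorption dip near
# 805 nm, ICG video frame stacks with a rendered laser indicator and known
# inflow onset/slope, sigmoid border images with known inflection, and
# cohort-level border-distance tables with known modality offsets.

#' Synthetic scenario configuration
#'
#' Bundles the generator parameters with their default study conditions.
#' Defaults: 160 x 120 px cubes on the 500-995 nm 5-nm grid (the full
#' 640 x 480 sensor size is reserved for demos), flat tissue baseline
#' reflectance 0.6, perfusion border at mid-image with a 6-px transition,
#' ICG dip of depth 0.2 centred at 805 nm (sigma 25 nm), 3 glare spots,
#' 0.5% multiplicative reflectance noise; inflow with T0 = 20 s, slope =
#' 20 units/s, a 12-s rise to plateau, 5 Hz video, curve-level SNR 20 and
#' an auto-gain laser dropping from 1.0 to 0.6 during inflow.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   deterministic (byte-identical reruns).
#' @param height,width,n_bands cube shape.
#' @param wavelengths_nm band grid.
#' @param baseline flat reflectance level or a per-band vector.
#' @param border_x0_px,border_w_px perfusion border centre (column) and
#'   logistic transition width in px.
#' @param perfusion_floor multiplicative reflectance level of the ischemic
#'   side relative to the perfused side.
#' @param icg list `(present, depth, center_nm, sigma_nm)`.
#' @param glare list `(n_spots, radius)`; glare sets all bands to 1.5.
#' @param noise_sd relative multiplicative reflectance noise sd.
#' @param inflow list `(t0_true_s, slope_true, plateau, rise_s, shape,
#'   frame_rate_hz, duration_s, snr, frame_height, frame_width)`;
#'   `plateau = NULL` derives `slope_true * rise_s`; `snr = Inf` is
#'   noiseless; `shape` is `"ramp"` or `"logistic"`.
#' @param laser list `(min_level, levels)`: auto-gain floor and the
#'   quantised indicator levels of the template bank.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            height = 120L, width = 160L, n_bands = 100L,
                            wavelengths_nm = seq(500, by = 5, length.out = n_bands),
                            baseline = 0.6,
                            border_x0_px = width / 2, border_w_px = 6,
                            perfusion_floor = 0.6,
                            icg = list(present = TRUE, depth = 0.2,
                                       center_nm = 805, sigma_nm = 25),
                            glare = list(n_spots = 3L, radius = 2),
                            noise_sd = 0.005,
                            inflow = list(t0_true_s = 20, slope_true = 20,
                                          plateau = NULL, rise_s = 12,
                                          shape = "ramp", frame_rate_hz = 5,
                                          duration_s = NULL, snr = 20,
                                          frame_height = 32L, frame_width = 48L),
                            laser = list(min_level = 0.6,
                                         levels = seq(0.1, 1, by = 0.1))) {
  if (!is_scalar_number(seed)) validation_error("seed must be a scalar")
  if (length(wavelengths_nm) != n_bands)
    validation_error("wavelength grid length must equal n_bands")
  if (!is.null(icg$depth) && (icg$depth < 0 || icg$depth >= 1))
    validation_error("icg depth must be in [0, 1)")
  if (border_x0_px < 1 || border_x0_px > width)
    validation_error("border_x0_px outside the image")
  if (noise_sd < 0) validation_error("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), height = as.integer(height),
                 width = as.integer(width), n_bands = as.integer(n_bands),
                 wavelengths_nm = wavelengths_nm, baseline = baseline,
                 border_x0_px = border_x0_px, border_w_px = border_w_px,
                 perfusion_floor = perfusion_floor, icg = icg, glare = glare,
                 noise_sd = noise_sd, inflow = inflow, laser = laser),
            class = "scenario_config")
}

#' Multiplicative ICG absorption factor
#'
#' Gaussian absorption dip: `factor(lambda) = 1 - depth *
#' exp(-(lambda - center)^2 / (2 sigma^2))`, minimal at the ICG absorption
#' maximum (approximately 805 nm in plasma).
#'
#' @param wavelengths_nm band grid in nm.
#' @param depth dip depth in `[0, 1)`.
#' @param center_nm dip centre, default 805.
#' @param sigma_nm dip width, default 25.
#' @return per-band multiplicative factor in `(0, 1]`.
#' @export
icg_absorption_factor <- function(wavelengths_nm, depth, center_nm = 805,
                                  sigma_nm = 25) {
  if (!is_scalar_number(depth) || depth < 0 || depth >= 1)
    validation_error("depth must be in [0, 1)")
  1 - depth * exp(-(wavelengths_nm - center_nm)^2 / (2 * sigma_nm^2))
}

#' Simulate a hyperspectral cube with ground truth
#'
#' Reflectance model per pixel and band:
#' `baseline(lambda) * (floor + (1 - floor) * perf(x)) *
#' (1 - conc(x) * depth * exp(-(lambda - 805)^2 / (2 sigma^2))) *
#' (1 + noise)`, where `perf(x) = conc(x) = 1 / (1 + exp((x - x0) / w))` is
#' the proximal-to-distal perfusion sigmoid (ICG accumulates only in
#' perfused tissue). Glare spots set all bands to 1.5; the cube is clipped
#' to be non-negative. Fully deterministic under the config seed.
#'
#' @param config a [scenario_config()].
#' @param acquisition_tag tag of the simulated acquisition.
#' @return list with `cube` (an [hs_cube()]) and `truth`
#'   (`border_x0_px`, `concentration` matrix, `glare_mask` matrix).
#' @export
simulate_cube <- function(config = scenario_config(), acquisition_tag = "intra") {
  set.seed(config$seed)
  H <- config$height; W <- config$width; B <- config$n_bands
  wl <- config$wavelengths_nm
  base <- if (length(config$baseline) == 1L) rep(config$baseline, B) else config$baseline
  if (length(base) != B) validation_error("baseline must be scalar or one value per band")
  w <- config$border_w_px
  xs <- seq_len(W)
  perf <- if (w > 0) 1 / (1 + exp((xs - config$border_x0_px) / w))
          else as.numeric(xs < config$border_x0_px)
  conc <- if (isTRUE(config$icg$present)) perf else rep(0, W)
  conc[conc < 0.01] <- 0  # compact support: <1% of peak concentration is none
  dip <- icg_absorption_factor(wl, if (isTRUE(config$icg$present)) config$icg$depth else 0,
                               config$icg$center_nm, config$icg$sigma_nm)
  g <- 1 - dip  # depth * gaussian
  mod <- config$perfusion_floor + (1 - config$perfusion_floor) * perf
  # per-column spectra: B x W
  col_mat <- outer(base, mod) * (1 - outer(g, conc))
  px_mat <- t(col_mat)[rep(seq_len(W), each = H), ]  # (H*W) x B, row-major r fastest
  noise <- matrix(stats::rnorm(H * W * B, sd = config$noise_sd), H * W, B)
  px_mat <- px_mat * (1 + noise)
  glare_mask <- matrix(FALSE, H, W)
  ng <- config$glare$n_spots
  if (ng > 0) {
    r <- config$glare$radius
    cx <- stats::runif(ng, 1 + r, W - r)
    cy <- stats::runif(ng, 1 + r, H - r)
    for (i in seq_len(ng)) {
      idx <- disc_indices(cx[i], cy[i], r, H, W)
      glare_mask[idx] <- TRUE
    }
    px_mat[as.vector(glare_mask), ] <- 1.5
  }
  arr <- array(clip(px_mat, 0, Inf), c(H, W, B))
  cube <- hs_cube(arr, wl, acquisition_tag,
                  meta = list(distance = "50 cm", dose = "0.1 mg/kg",
                              synthetic = "true"))
  list(cube = cube,
       truth = list(border_x0_px = config$border_x0_px,
                    concentration = matrix(rep(conc, each = H), H, W),
                    glare_mask = glare_mask))
}

#' Simulate an ICG inflow video with ground truth
#'
#' The ROI-region fluorescence follows baseline zero until `t0_true_s`,
#' then rises (ramp or logistic) with known maximal slope to the plateau.
#' An auto-gain laser level starts at 1.0 and drops to `min_level` during
#' the rise; it is quantised to the template-bank levels, rendered into
#' the top-right indicator region, and scales the recorded fluorescence.
#' Per-pixel Gaussian sensor noise of sd `plateau / snr` is added to every
#' frame (`raw = fluorescence * laser + noise`); averaging over the ROI
#' disc reduces its effect on the extracted curve by the square root of
#' the ROI pixel count.
#'
#' @param config a [scenario_config()].
#' @return list with `stack` (a [frame_stack()]), `roi`, `indicator`,
#'   `bank`, and `truth` (`t0_true_s`, `slope_true`, `plateau`,
#'   `laser_series`, `fluor_series`, `t_s`).
#' @export
simulate_inflow_stack <- function(config = scenario_config()) {
  set.seed(config$seed + 1L)
  inf <- config$inflow
  fr <- inf$frame_rate_hz
  rise <- inf$rise_s
  plateau <- if (is.null(inf$plateau)) inf$slope_true * rise else inf$plateau
  if (!is.null(inf$plateau)) rise <- plateau / inf$slope_true
  t0 <- inf$t0_true_s
  dur <- if (is.null(inf$duration_s)) t0 + rise + 15 else inf$duration_s
  if (t0 >= dur) validation_error("t0_true_s must be before the stack end")
  n <- as.integer(round(dur * fr)) + 1L
  t <- (seq_len(n) - 1L) / fr
  fluor <- switch(inf$shape,
    ramp = clip(inf$slope_true * (t - t0), 0, plateau),
    logistic = plateau / (1 + exp(-(4 * inf$slope_true / plateau) * (t - t0 - rise / 2))),
    validation_error("inflow shape must be 'ramp' or 'logistic'"))
  noise_sd <- if (is.finite(inf$snr)) plateau / inf$snr else 0
  lvl_raw <- 1 - (1 - config$laser$min_level) * clip((t - t0) / rise, 0, 1)
  bank <- laser_template_bank(config$laser$levels)
  lvl_idx <- vapply(lvl_raw, function(L) {
    d <- abs(bank$levels - L)
    max(which(d <= min(d) + 1e-12))
  }, 0L)
  lvl <- bank$levels[lvl_idx]
  H <- inf$frame_height; W <- inf$frame_width
  td <- dim(bank$templates[[1]])
  indicator <- list(x = W - td[2] + 1L, y = 1L, w = td[2], h = td[1])
  roi <- circular_roi(x = floor(W / 2) - 4, y = floor(H / 2) + 2, r = 8,
                      label = "proximal", perfusion_class = "perfused")
  signal_idx <- disc_indices(roi$x, roi$y, roi$r + 2, H, W)
  m <- matrix(if (noise_sd > 0) stats::rnorm(H * W * n, sd = noise_sd) else 0, H * W, n)
  m[signal_idx, ] <- m[signal_idx, ] + rep(fluor * lvl, each = length(signal_idx))
  ind_idx <- as.vector(outer((indicator$y):(indicator$y + td[1] - 1L),
                             ((indicator$x):(indicator$x + td[2] - 1L) - 1L) * H, "+"))
  for (k in unique(lvl_idx))
    m[ind_idx, lvl_idx == k] <- as.vector(bank$templates[[k]])
  stack <- frame_stack(array(m, c(H, W, n)), fr)
  list(stack = stack, roi = roi, indicator = indicator, bank = bank,
       truth = list(t0_true_s = t0, slope_true = inf$slope_true,
                    plateau = plateau, laser_series = lvl,
                    fluor_series = fluor, t_s = t))
}

#' Simulate a border intensity image with known inflection
#'
#' A falling logistic along the proximal-to-distal (column) axis:
#' `low + (high - low) / (1 + exp((x - x0) / w))` plus i.i.d. Gaussian
#' noise; `w = 0` produces a step edge.
#'
#' @param height,width image size in px.
#' @param x0_px true inflection column.
#' @param w_px transition width in px.
#' @param high,low plateau intensities.
#' @param noise_sd absolute noise sd (e.g. 5% of `high - low`).
#' @param seed RNG seed.
#' @return list with `image` (matrix) and `truth` (`x0_px`).
#' @export
simulate_border_image <- function(height = 120L, width = 160L, x0_px = 80,
                                  w_px = 6, high = 200, low = 20,
                                  noise_sd = 0, seed = 1L) {
  if (x0_px < 1 || x0_px > width) validation_error("x0_px outside the image")
  set.seed(seed)
  xs <- seq_len(width)
  prof <- if (w_px > 0) low + (high - low) / (1 + exp((xs - x0_px) / w_px))
          else ifelse(xs < x0_px, high, low)
  img <- matrix(rep(prof, each = height), height, width)
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(height * width, sd = noise_sd),
                                        height, width)
  list(image = img, truth = list(x0_px = x0_px))
}

#' Simulate a cohort of per-case border distances
#'
#' Generates the per-case, per-modality signed border distances (cm to the
#' clinical marker) that the border-geometry stage would emit: each
#' distance is the modality's true offset plus i.i.d. Gaussian
#' measurement noise. Deterministic under the seed; the truth table is
#' returned alongside.
#'
#' @param n_cases number of cases (>= 3).
#' @param offsets_cm named numeric vector of true per-modality offsets,
#'   e.g. `c(ICG = 0, recICG = 0, StO2 = 0.24)`.
#' @param sd_cm measurement noise sd in cm (> 0).
#' @param seed RNG seed.
#' @return list with `distances` (data frame `case`, `modality`,
#'   `distance_cm`) and `truth` (`offsets_cm`, `sd_cm`).
#' @export
simulate_cohort <- function(n_cases, offsets_cm, sd_cm = 0.2, seed = 1L) {
  if (n_cases < 3L) validation_error("a cohort needs at least 3 cases")
  if (is.null(names(offsets_cm)) || any(!nzchar(names(offsets_cm))))
    validation_error("offsets_cm must be a named vector")
  if (!is_scalar_number(sd_cm) || sd_cm <= 0)
    validation_error("sd_cm must be a positive scalar")
  set.seed(seed)
  mods <- names(offsets_cm)
  distances <- do.call(rbind, lapply(seq_len(n_cases), function(i) {
    data.frame(case = sprintf("case_%03d", i), modality = mods,
               distance_cm = offsets_cm + stats::rnorm(length(mods), sd = sd_cm),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(distances = distances, truth = list(offsets_cm = offsets_cm, sd_cm = sd_cm))
}
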