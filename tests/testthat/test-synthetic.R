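test_that("ICG absorption factor follows the Gaussian dip formula", {
  wl <- seq(500, by = 5, length.out = 100)
  expect_equal(icg_absorption_factor(wl, 0), rep(1, 100))
  f <- icg_absorption_factor(wl, 0.2)
  expect_equal(f[wl == 805], 0.8)
  expect_identical(which.min(f), which.min(abs(wl - 805)))
  expect_error(icg_absorption_factor(wl, 1), class = "icgperf_validation_error")
})

test_that("simulated cubes are deterministic and satisfy consumer invariants", {
  cfg <- scenario_config(seed = 111, height = 24L, width = 40L)
  a <- simulate_cube(cfg)
  b <- simulate_cube(cfg)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$truth$glare_mask, b$truth$glare_mask)

  set.seed(112)
  for (i in 1:10) {
    cfg_i <- scenario_config(seed = 200 + i, height = 20L, width = 30L,
                             border_x0_px = runif(1, 8, 22),
                             border_w_px = runif(1, 2, 8),
                             icg = list(present = i %% 2 == 0,
                                        depth = runif(1, 0.05, 0.4),
                                        center_nm = 805, sigma_nm = 25),
                             glare = list(n_spots = sample(0:3, 1), radius = 1.5),
                             noise_sd = runif(1, 0, 0.02))
    sim <- simulate_cube(cfg_i)
    expect_s3_class(sim$cube, "hs_cube")  # constructor enforces invariants
    expect_true(all(sim$cube$data >= 0))
    expect_true(all(sim$cube$data[rep(as.vector(sim$truth$glare_mask), 100)] == 1.5))
  }
})

test_that("ICG-on and ICG-off cubes agree bitwise outside the concentration support", {
  cfg_on <- scenario_config(seed = 113, height = 20L, width = 80L,
                            glare = list(n_spots = 0L, radius = 2))
  cfg_off <- cfg_on
  cfg_off$icg$present <- FALSE
  on <- simulate_cube(cfg_on)
  off <- simulate_cube(cfg_off)
  outside <- which(on$truth$concentration[1, ] == 0)
  expect_gt(length(outside), 5)
  expect_identical(on$cube$data[, outside, ], off$cube$data[, outside, ])
  inside <- which(on$truth$concentration[1, ] > 0.5)
  expect_false(identical(on$cube$data[, inside, ], off$cube$data[, inside, ]))
})

test_that("reconstruction on a simulated ICG cube splits the region medians", {
  sim <- simulate_cube(scenario_config(seed = 114))
  rec <- reconstruct_icg(sim$cube)
  conc <- sim$truth$concentration
  expect_gte(median(rec$values[conc > 0.95]), 0.9)
  expect_lte(median(rec$values[conc < 0.05]), 0.05)
})

test_that("simulated inflow stacks are deterministic with consistent truth", {
  cfg <- scenario_config(seed = 115)
  a <- simulate_inflow_stack(cfg)
  b <- simulate_inflow_stack(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$laser_series, b$truth$laser_series)

  # the rendered indicator is recovered level-for-level by template matching
  lv <- estimate_laser_series(a$stack, a$indicator, a$bank)
  expect_equal(lv, a$truth$laser_series)
})

test_that("a noiseless ramp is recovered exactly through the full pipeline", {
  cfg <- scenario_config(seed = 116,
                         inflow = list(t0_true_s = 20, slope_true = 20,
                                       plateau = NULL, rise_s = 12,
                                       shape = "ramp", frame_rate_hz = 5,
                                       duration_s = NULL, snr = Inf,
                                       frame_height = 32L, frame_width = 48L))
  si <- simulate_inflow_stack(cfg)
  cv <- build_curve(si$stack, si$roi, si$indicator, si$bank)
  m <- inflow_metrics(cv)
  expect_lte(abs(m$t0_objective_s - 20), 1 / 5 + 1e-9)  # one frame
  expect_equal(m$slope_units_per_s, 20, tolerance = 1e-9)
  expect_equal(m$background_noise_B, 0)
})

test_that("a constant laser leaves the normalized curve equal to the fluorescence", {
  cfg <- scenario_config(seed = 117,
                         laser = list(min_level = 1, levels = seq(0.1, 1, by = 0.1)))
  si <- simulate_inflow_stack(cfg)
  expect_true(all(si$truth$laser_series == 1))
  cv <- build_curve(si$stack, si$roi, si$indicator, si$bank)
  # ROI mean of signal disc: ROI strictly inside the rendered signal disc
  resid <- cv$normalized - si$truth$fluor_series
  expect_lt(max(abs(resid)), 6 * sd(resid) + 1e-6)  # pure noise residual
  cor_ok <- cor(cv$normalized, si$truth$fluor_series)
  expect_gt(cor_ok, 0.99)
})

test_that("border images honour their truth and degenerate limits", {
  nb <- simulate_border_image(x0_px = 70, noise_sd = 0)
  pr <- sample_profile(nb$image, c(5, 60), c(155, 60))
  expect_lt(abs((5 + inflection_geometric(pr)) - 70), 0.5 + 1e-9)

  st <- simulate_border_image(x0_px = 70, w_px = 0, noise_sd = 0)
  expect_true(all(st$image[, 1:69] == 200))
  expect_true(all(st$image[, 70:160] == 20))
  pr2 <- sample_profile(st$image, c(5, 60), c(155, 60))
  expect_lt(abs((5 + inflection_geometric(pr2)) - 70), 1)

  expect_error(simulate_border_image(x0_px = 500),
               class = "icgperf_validation_error")
})

test_that("cohort simulation is deterministic and centred on its offsets", {
  offs <- c(ICG = -0.1, recICG = -0.15, StO2 = 0.24)
  a <- simulate_cohort(40, offs, sd_cm = 0.2, seed = 118)
  b <- simulate_cohort(40, offs, sd_cm = 0.2, seed = 118)
  expect_identical(a$distances, b$distances)
  for (m in names(offs)) {
    got <- mean(a$distances$distance_cm[a$distances$modality == m])
    expect_lt(abs(got - offs[[m]]), 0.1)
  }
  expect_error(simulate_cohort(2, offs), class = "icgperf_validation_error")
})
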