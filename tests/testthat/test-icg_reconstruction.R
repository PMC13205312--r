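test_that("spectral smoothing preserves constants and interior linear trends", {
  b <- 100L
  wl <- seq(500, by = 5, length.out = b)
  flat <- hs_cube(array(0.5, c(4, 4, b)), wl)
  expect_equal(smooth_spectra(flat)$data, flat$data, tolerance = 1e-12)

  lin <- hs_cube(array(rep(seq(0.1, 0.6, length.out = b), each = 16), c(4, 4, b)), wl)
  sm <- smooth_spectra(lin)
  r <- ceiling(4 * 4.44)
  interior <- (r + 1):(b - r)
  expect_equal(sm$data[2, 3, interior], lin$data[2, 3, interior], tolerance = 1e-12)

  expect_error(smooth_spectra(hs_cube(array(0.5, c(2, 2, 2)), c(500, 505))),
               class = "icgperf_validation_error")
})

test_that("spectral smoothing matches direct-summation convolution", {
  cube <- make_test_cube(21, h = 6L, w = 5L)
  sm <- smooth_spectra(cube)
  expect_lt(max(abs(sm$data - o_gauss_smooth(cube$data, 4.44))), 1e-9)
  # a different sigma exercises the kernel construction
  sm2 <- smooth_spectra(cube, sigma_bands = 2)
  expect_lt(max(abs(sm2$data - o_gauss_smooth(cube$data, 2))), 1e-9)
})

test_that("spectral second derivative is exact for polynomials and matches the oracle", {
  b <- 100L
  wl <- seq(500, by = 5, length.out = b)
  flat <- hs_cube(array(0.7, c(3, 3, b)), wl)
  expect_equal(max(abs(spectral_second_derivative(flat)$data)), 0)

  a <- 1e-6
  quad <- hs_cube(array(rep(a * wl^2, each = 9), c(3, 3, b)), wl)
  d2 <- spectral_second_derivative(quad)
  expect_equal(d2$data[2, 2, 2:(b - 1)], rep(2 * a, b - 2), tolerance = 1e-9)
  expect_equal(d2$data[2, 2, 1], d2$data[2, 2, 2])  # edge replication

  cube <- make_test_cube(22, h = 5L, w = 4L)
  expect_lt(max(abs(spectral_second_derivative(cube)$data -
                      o_second_deriv(cube$data, wl))), 1e-9)

  bad <- hs_cube(array(0.5, c(2, 2, 4)), c(500, 505, 512, 520))
  expect_error(spectral_second_derivative(bad), class = "icgperf_validation_error")
})

dip_cube <- function(depth = 0.2, h = 20L, w = 40L, baseline = 0.6) {
  # left half carries the multiplicative ICG dip, right half flat
  b <- 100L
  wl <- seq(500, by = 5, length.out = b)
  fac <- 1 - depth * exp(-(wl - 805)^2 / (2 * 25^2))
  arr <- array(baseline, c(h, w, b))
  arr[, 1:(w / 2), ] <- rep(baseline * fac, each = h * w / 2) |>
    array(c(h, w / 2, b))
  hs_cube(arr, wl, "intra")
}

test_that("reconstruction separates the ICG dip region from flat tissue", {
  cube <- dip_cube(0.2)
  rec <- reconstruct_icg(cube)
  expect_true(all(rec$values >= 0 & rec$values <= 1))
  expect_gte(median(rec$values[, 1:18]), 0.9)
  expect_lte(median(rec$values[, 23:40]), 0.05)

  # spectrally linear cube: zero curvature, zero-percentile guard
  b <- 100L
  wl <- seq(500, by = 5, length.out = b)
  lin <- hs_cube(array(rep(0.2 + 0.001 * (wl - 500), each = 100), c(10, 10, b)), wl, "post")
  expect_equal(max(abs(reconstruct_icg(lin)$values)), 0)

  # window not covered
  nir <- hs_cube(array(0.5, c(4, 4, 20)), seq(500, by = 5, length.out = 20))
  expect_error(reconstruct_icg(nir), class = "icgperf_range_error")
})

test_that("reconstruction equals the staged brute-force oracle", {
  for (seed in c(31, 32)) {
    cube <- make_test_cube(seed, h = 8L, w = 8L)
    pre <- o_recicg_prenorm(cube$data, cube$wavelengths_nm)
    # package result before normalisation, rebuilt from exported stages
    sm <- smooth_spectra(cube)
    d2 <- spectral_second_derivative(sm)
    keep <- cube$wavelengths_nm >= 790 & cube$wavelengths_nm <= 810
    score <- apply(d2$data[, , keep], c(1, 2), mean)
    score[score < 0] <- 0
    expect_lt(max(abs(score - pre)), 1e-9)
    # full pipeline vs oracle stages (median filter + percentile + clip)
    med <- o_median_filter(pre, 7L)
    p99 <- as.numeric(quantile(med, 0.99, names = FALSE))
    want <- if (p99 <= 1e-12) med * 0 else pmin(pmax(med / p99, 0), 1)
    expect_equal(reconstruct_icg(cube)$values, want, tolerance = 1e-12)
  }
})

test_that("isolated glare pixels barely perturb the reconstruction", {
  cube <- dip_cube(0.2)
  rec0 <- reconstruct_icg(cube)
  set.seed(5)
  n_glare <- round(0.01 * 20 * 40)
  idx <- sample(20 * 40, n_glare)
  arr <- cube$data
  m <- matrix(arr, 20 * 40, 100)
  m[idx, ] <- 1.5
  glared <- hs_cube(array(m, dim(arr)), cube$wavelengths_nm, "intra")
  rec1 <- reconstruct_icg(glared)
  expect_lt(abs(median(rec1$values[, 1:18]) - median(rec0$values[, 1:18])), 0.02)
  expect_lt(abs(median(rec1$values[, 23:40]) - median(rec0$values[, 23:40])), 0.02)
})

test_that("output is invariant under global multiplicative rescaling", {
  cube <- make_test_cube(33, h = 8L, w = 8L)
  rec1 <- reconstruct_icg(cube)
  scaled <- hs_cube(cube$data * 3.7, cube$wavelengths_nm, cube$acquisition_tag)
  rec2 <- reconstruct_icg(scaled)
  expect_equal(rec1$values, rec2$values, tolerance = 1e-12)
})

test_that("deeper 805-nm absorption never lowers the curvature score", {
  b <- 100L
  wl <- seq(500, by = 5, length.out = b)
  prev <- -Inf
  for (depth in c(0.05, 0.1, 0.2, 0.3, 0.4)) {
    fac <- 1 - depth * exp(-(wl - 805)^2 / (2 * 25^2))
    cube <- hs_cube(array(rep(0.6 * fac, each = 9), c(3, 3, b)), wl)
    sm <- smooth_spectra(cube)
    d2 <- spectral_second_derivative(sm)
    keep <- wl >= 790 & wl <= 810
    score <- mean(d2$data[2, 2, keep])
    expect_gt(score, prev)
    prev <- score
  }
})
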