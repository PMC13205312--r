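test_that("ruler calibration is the known length over the pixel distance", {
  expect_equal(calibrate_scale(c(0, 0), c(100, 0), 1), 0.01)
  expect_equal(calibrate_scale(c(0, 0), c(3, 4), 1), 0.2)
  expect_error(calibrate_scale(c(5, 5), c(5, 5), 1), class = "icgperf_validation_error")
})

test_that("profile sampling is exact bilinear interpolation", {
  const <- matrix(7, 30, 40)
  pr <- sample_profile(const, c(2, 15), c(38, 15))
  expect_true(all(pr$values == 7))
  expect_equal(diff(pr$positions_px), rep(0.5, length(pr$positions_px) - 1))

  grad <- matrix(rep(1:40, each = 30), 30, 40)  # value = x coordinate
  pr2 <- sample_profile(grad, c(3, 10), c(37, 10))
  expect_equal(pr2$values, 3 + pr2$positions_px, tolerance = 1e-12)

  set.seed(81)
  img <- matrix(cumsum(rnorm(30 * 40)), 30, 40)
  pr3 <- sample_profile(img, c(4, 5), c(33, 24), step_px = 0.7)
  u <- (c(33, 24) - c(4, 5)) / sqrt(sum((c(33, 24) - c(4, 5))^2))
  for (i in seq(1, length(pr3$positions_px), by = 7)) {
    p <- c(4, 5) + pr3$positions_px[i] * u
    expect_equal(pr3$values[i], o_bilinear(img, p[1], p[2]))
  }

  expect_error(sample_profile(const, c(2, 15), c(45, 15)),
               class = "icgperf_range_error")
})

logistic_profile <- function(x0, width = 8, n = 201, high = 100, noise_sd = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- seq(0, 100, length.out = n)
  vals <- high / (1 + exp((pos - x0) / width)) + rnorm(n, sd = noise_sd)
  structure(list(positions_px = pos, values = vals,
                 direction = c(1, 0), origin_xy = c(1, 1)),
            class = "line_profile")
}

test_that("geometric inflection recovers a noiseless sigmoid within one sample", {
  for (x0 in c(35, 50, 62)) {
    pr <- logistic_profile(x0)
    expect_lt(abs(inflection_geometric(pr) - x0), 0.5 + 1e-9)
  }
  # a linear profile has no chord deviation: degenerate
  lin <- structure(list(positions_px = seq(0, 100, length.out = 101),
                        values = seq(100, 0, length.out = 101),
                        direction = c(1, 0), origin_xy = c(0, 0)),
                   class = "line_profile")
  expect_error(inflection_geometric(lin), class = "icgperf_degenerate_error")
})

test_that("geometric inflection is robust to 5% noise and matches the scan oracle", {
  errs <- sapply(1:100, function(seed) {
    pr <- logistic_profile(50, noise_sd = 5, seed = seed)
    est <- inflection_geometric(pr)
    expect_equal(est, o_inflection(pr$positions_px, pr$values), tolerance = 1e-9)
    abs(est - 50)
  })
  expect_lte(median(errs), 2 * 0.5)  # two sample spacings
})

test_that("inflection is exactly invariant under affine intensity maps", {
  pr <- logistic_profile(44, noise_sd = 4, seed = 9)
  base <- inflection_geometric(pr)
  for (ab in list(c(2.5, 0), c(1, 30), c(0.3, -12))) {
    pr2 <- pr
    pr2$values <- ab[1] * pr$values + ab[2]
    expect_identical(inflection_geometric(pr2), base)
  }
})

border_images <- function(offsets_px, x0 = 80, seed = 1) {
  imgs <- lapply(seq_along(offsets_px), function(i)
    simulate_border_image(x0_px = x0 + offsets_px[i], noise_sd = 2,
                          seed = seed + i)$image)
  names(imgs) <- names(offsets_px)
  imgs
}

three_profiles <- list(list(p0 = c(10, 30), p1 = c(150, 30)),
                       list(p0 = c(10, 60), p1 = c(150, 60)),
                       list(p0 = c(10, 90), p1 = c(150, 90)))

test_that("border distances recover known per-modality offsets", {
  # border exactly at the marker
  imgs <- border_images(c(ICG = 0))
  bd <- border_distances(imgs, three_profiles, marker_xy = c(80, 60),
                         scale_cm_per_px = 0.01)
  expect_lt(abs(bd$signed_distance_cm), 0.01)

  # +50 px distal at 0.01 cm/px is +0.5 cm
  imgs2 <- border_images(c(ICG = 50), x0 = 60)
  bd2 <- border_distances(imgs2, three_profiles, marker_xy = c(60, 60),
                          scale_cm_per_px = 0.01)
  expect_equal(bd2$signed_distance_cm, 0.5, tolerance = 0.03)

  # the three-modality constellation of the study design
  offs <- c(ICG = -10, recICG = -15, StO2 = 24)
  bd3 <- border_distances(border_images(offs), three_profiles,
                          marker_xy = c(80, 60), scale_cm_per_px = 0.01)
  expect_equal(bd3$signed_distance_cm[match(names(offs), bd3$modality)],
               unname(offs) * 0.01, tolerance = 0.03)
})

test_that("border distances are translation-equivariant and flip-antisymmetric", {
  offs <- c(A = -12)
  imgs <- border_images(offs, x0 = 70)
  bd <- border_distances(imgs, three_profiles, c(70, 60), 0.01)

  # translate image content and annotations together by (+5, +7)
  shift <- function(img, dx, dy) {
    out <- img * 0 + img[1, 1]
    out[(1 + dy):nrow(img), (1 + dx):ncol(img)] <-
      img[1:(nrow(img) - dy), 1:(ncol(img) - dx)]
    out
  }
  imgs_s <- lapply(imgs, shift, dx = 5, dy = 7)
  prof_s <- lapply(three_profiles, function(p)
    list(p0 = p$p0 + c(5, 7), p1 = p$p1 + c(5, 7)))
  bd_s <- border_distances(imgs_s, prof_s, c(75, 67), 0.01)
  expect_equal(bd_s$signed_distance_cm, bd$signed_distance_cm, tolerance = 1e-9)

  # swapping p0/p1 negates the proximal->distal axis and the sign
  prof_f <- lapply(three_profiles, function(p) list(p0 = p$p1, p1 = p$p0))
  bd_f <- border_distances(imgs, prof_f, c(70, 60), 0.01)
  expect_equal(bd_f$signed_distance_cm, -bd$signed_distance_cm, tolerance = 1e-9)
})

test_that("degenerate profiles are dropped; all-degenerate modalities error", {
  flat <- list(F = matrix(5, 120, 160))
  expect_error(
    suppressWarnings(border_distances(flat, three_profiles, c(80, 60), 0.01)),
    class = "icgperf_degenerate_error")

  # one flat stripe: that profile is dropped with a warning, median of the rest
  img <- simulate_border_image(x0_px = 80, noise_sd = 0)$image
  img[85:95, ] <- 42  # flattens the third profile line (y = 90)
  expect_warning(
    bd <- border_distances(list(M = img), three_profiles, c(80, 60), 0.01),
    "degenerate")
  expect_true(is.na(bd$inflection_px_3))
  expect_lt(abs(bd$signed_distance_cm), 0.02)
})
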