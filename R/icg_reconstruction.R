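# Reconstruction of an ICG-mimicking absorption image from hyperspectral
# reflectance. ICG absorbs maximally near 805 nm; during/after intravenous
# administration the reflectance spectrum of perfused tissue carries a dip
# there, whose curvature (spectral second derivative) is averaged over the
# 790-810 nm window to form the reconstructed image.

#' Smooth cube spectra with a 1-d Gaussian along the band axis
#'
#' Per-pixel Gaussian convolution along wavelength only; spatial content is
#' untouched. The kernel has standard deviation `sigma_bands` in band-index
#' units (the default 4.44 corresponds to about 22 nm on the nominal 5-nm
#' grid), is truncated at radius `ceiling(4 * sigma_bands)` and normalised
#' to unit sum; spectra are reflect-padded (edge sample included) at both
#' spectral ends.
#'
#' @param cube an [hs_cube()] with at least 3 bands.
#' @param sigma_bands Gaussian standard deviation in band-index units (> 0).
#' @return an [hs_cube()] with smoothed spectra on the same grid.
#' @export
smooth_spectra <- function(cube, sigma_bands = 4.44) {
  if (!inherits(cube, "hs_cube")) validation_error("cube must be an hs_cube")
  if (!is_scalar_number(sigma_bands) || sigma_bands <= 0)
    validation_error("sigma_bands must be a positive scalar")
  b <- length(cube$wavelengths_nm)
  if (b < 3L) validation_error("spectral smoothing needs at least 3 bands")
  r <- as.integer(ceiling(4 * sigma_bands))
  kern <- exp(-(seq.int(-r, r))^2 / (2 * sigma_bands^2))
  kern <- kern / sum(kern)
  # reflect (symmetric, edge included) pad indices: ... 2 1 | 1 2 ... b | b b-1 ...
  pad_idx <- c(rev(seq_len(min(r, b))), seq_len(b), rev(seq.int(max(1L, b - r + 1L), b)))
  # if r > b the simple reflection is too short; extend by cyclic reflection
  while (length(pad_idx) < b + 2L * r) {
    pad_idx <- c(pad_idx[1], pad_idx, pad_idx[length(pad_idx)])
  }
  # build (b + 2r) x b weight matrix: column k holds the kernel centred at k + r
  wmat <- matrix(0, b + 2L * r, b)
  for (k in seq_len(b)) wmat[(k):(k + 2L * r), k] <- kern
  m <- matrix(cube$data, cube$height * cube$width, b)
  sm <- m[, pad_idx, drop = FALSE] %*% wmat
  out <- cube
  out$data <- array(clip(sm, 0, Inf), dim(cube$data))
  out
}

#' Spectral second derivative of a cube
#'
#' Central second difference along the band axis on a uniform wavelength
#' grid: `(R[k-1] - 2 R[k] + R[k+1]) / dlambda^2` at interior bands, in
#' units of reflectance per nm^2. Edge bands replicate the nearest interior
#' value.
#'
#' @param cube an [hs_cube()] on a uniform grid with >= 3 bands.
#' @return an [hs_cube()]-shaped object whose `data` holds per-band
#'   curvature (values may be negative; the cube invariants for reflectance
#'   do not apply, so a plain list with the same fields is returned).
#' @export
spectral_second_derivative <- function(cube) {
  wl <- cube$wavelengths_nm
  b <- length(wl)
  if (b < 3L) validation_error("second derivative needs at least 3 bands")
  dl <- diff(wl)
  if (max(abs(dl - dl[1])) > 1e-6 * dl[1])
    validation_error("wavelength grid is not uniform; resample the cube before differentiating")
  h2 <- dl[1]^2
  m <- matrix(cube$data, cube$height * cube$width, b)
  d2 <- matrix(0, nrow(m), b)
  ki <- 2:(b - 1L)
  d2[, ki] <- (m[, ki - 1L] - 2 * m[, ki] + m[, ki + 1L]) / h2
  d2[, 1L] <- d2[, 2L]
  d2[, b] <- d2[, b - 1L]
  out <- unclass(cube)
  out$data <- array(d2, dim(cube$data))
  class(out) <- c("hs_curvature", "hs_cube")
  out
}

median_filter_2d <- function(img, k = 7L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) config_error("median kernel size must be odd and >= 1")
  if (k == 1L) return(img)
  r <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  # reflect (symmetric) padding
  ridx <- c(rev(seq_len(min(r, nr))), seq_len(nr), rev(seq.int(max(1L, nr - r + 1L), nr)))
  cidx <- c(rev(seq_len(min(r, nc))), seq_len(nc), rev(seq.int(max(1L, nc - r + 1L), nc)))
  pad <- img[ridx, cidx, drop = FALSE]
  stackm <- matrix(0, nr * nc, k * k)
  j <- 0L
  for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
    j <- j + 1L
    stackm[, j] <- as.vector(pad[dr + seq_len(nr), dc + seq_len(nc)])
  }
  matrix(apply(stackm, 1L, stats::median), nr, nc)
}

#' Reconstruct an ICG absorption image from a hyperspectral cube
#'
#' Produces the normalised reconstructed-ICG map: spectra are Gaussian
#' smoothed along wavelength, differentiated twice spectrally, and the
#' curvature is averaged over the bands whose centres lie in the closed
#' `band_window_nm` (790-810 nm by default: 5 bands on the nominal grid).
#' Negative curvature is clipped to zero (the ICG dip produces positive
#' curvature at its minimum; negative values stem from noise and other
#' chromophores), the map is median filtered (`median_kernel` square,
#' reflect padding) and divided by its `percentile`-th percentile over the
#' whole image, then clipped to `[0, 1]`. If that percentile is <= 1e-12
#' the output is identically zero.
#'
#' @param cube an [hs_cube()] acquired during or after ICG administration;
#'   the grid must cover the smoothing-widened band window.
#' @param sigma_bands spectral Gaussian standard deviation in band units.
#' @param band_window_nm closed wavelength window `[lo, hi]` in nm.
#' @param median_kernel odd spatial median kernel size in pixels.
#' @param percentile normalisation percentile in (0, 100].
#' @return an object of class `rec_icg_image` with `values` (matrix in
#'   `[0, 1]`), `source_tag` and `params`.
#' @export
reconstruct_icg <- function(cube, sigma_bands = 4.44, band_window_nm = c(790, 810),
                            median_kernel = 7L, percentile = 99) {
  wl <- cube$wavelengths_nm
  dl <- if (length(wl) > 1) wl[2] - wl[1] else 0
  need_lo <- band_window_nm[1] - ceiling(4 * sigma_bands) * dl
  need_hi <- band_window_nm[2] + ceiling(4 * sigma_bands) * dl
  if (wl[1] > band_window_nm[1] || wl[length(wl)] < band_window_nm[2])
    range_error(sprintf("cube grid [%.0f, %.0f] nm does not cover the %.0f-%.0f nm window",
                        wl[1], wl[length(wl)], band_window_nm[1], band_window_nm[2]))
  if (wl[1] > need_lo || wl[length(wl)] < need_hi)
    warning("cube grid does not cover the full smoothing support of the band window; edge padding affects the result")
  sm <- smooth_spectra(cube, sigma_bands)
  d2 <- spectral_second_derivative(sm)
  in_win <- wl >= band_window_nm[1] & wl <= band_window_nm[2]
  if (!any(in_win)) range_error("no band centres inside the band window")
  b <- length(wl)
  m <- matrix(d2$data, cube$height * cube$width, b)
  score <- rowMeans(m[, in_win, drop = FALSE])
  score <- clip(score, 0, Inf)
  img <- matrix(score, cube$height, cube$width)
  img <- median_filter_2d(img, median_kernel)
  p <- as.numeric(stats::quantile(img, percentile / 100, names = FALSE))
  values <- if (p <= 1e-12) matrix(0, cube$height, cube$width) else clip(img / p, 0, 1)
  structure(list(
    values = values,
    source_tag = cube$acquisition_tag,
    params = list(sigma_bands = sigma_bands, band_window_nm = band_window_nm,
                  median_kernel = median_kernel, percentile = percentile)
  ), class = "rec_icg_image")
}

#' @export
print.rec_icg_image <- function(x, ...) {
  cat(sprintf("<rec_icg_image> %d x %d, tag '%s', range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$source_tag,
              min(x$values), max(x$values)))
  invisible(x)
}
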