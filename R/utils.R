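# Internal helpers shared across modules.

#' @keywords internal
abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "icgperf_error", "error")))
}

validation_error <- function(msg, ...) abort(msg, "icgperf_validation_error", ...)
range_error      <- function(msg, ...) abort(msg, "icgperf_range_error", ...)
format_error     <- function(msg, ...) abort(msg, "icgperf_format_error", ...)
shape_error      <- function(msg, ...) abort(msg, "icgperf_shape_error", ...)
config_error     <- function(msg, ...) abort(msg, "icgperf_config_error", ...)
degenerate_error <- function(msg, ...) abort(msg, "icgperf_degenerate_error", ...)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Centred moving average with symmetric shrinking endpoints
#'
#' Smooths a numeric vector with a centred window of `k` samples (`k` is
#' forced odd by adding one if even). Near the ends the window shrinks
#' symmetrically: at index `i` the half-width is
#' `min((k - 1) / 2, i - 1, n - i)`, so constants are preserved everywhere.
#'
#' @param x numeric vector.
#' @param k window length in samples (>= 1).
#' @return numeric vector of the same length as `x`.
#' @export
movmean <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- as.integer(k)
  if (k < 1L) validation_error("movmean window must be >= 1")
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  hw <- pmin(h, i - 1L, n - i)
  (cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1)
}

# Linear pixel indices (into an nrow x ncol matrix) of the disc of radius r
# around centre (x = col, y = row); membership is dx^2 + dy^2 <= r^2 on
# pixel centres.
disc_indices <- function(cx, cy, r, nrow, ncol) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow, ceiling(cy + r))
  xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
  dx2 <- (xs - cx)^2; dy2 <- (ys - cy)^2
  inside <- outer(dy2, dx2, "+") <= r^2
  rows <- rep(ys, times = length(xs))[inside]
  cols <- rep(xs, each = length(ys))[inside]
  (cols - 1L) * nrow + rows
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
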