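# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops and base arithmetic, never
# calling the package's vectorised implementations.

# symmetric (edge-repeating) reflection of index i into 1..n
o_reflect <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# per-pixel Gaussian smoothing along bands: for every pixel, each output
# band is the kernel dot product with an explicitly reflect-padded window
o_gauss_smooth <- function(arr, sigma) {
  d <- dim(arr)
  b <- d[3]
  r <- as.integer(ceiling(4 * sigma))
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  win <- matrix(0L, b, 2L * r + 1L)  # window index k + m, reflected into 1..b
  for (k in seq_len(b)) for (m in (-r):r)
    win[k, m + r + 1L] <- o_reflect(k + m, b)
  out <- arr
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sp <- arr[i, j, ]
    out[i, j, ] <- as.vector(matrix(sp[win], b, 2L * r + 1L) %*% kern)
  }
  out
}

# central second difference per pixel, edge replication
o_second_deriv <- function(arr, wavelengths) {
  d <- dim(arr)
  b <- d[3]
  h2 <- (wavelengths[2] - wavelengths[1])^2
  out <- arr * 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    sp <- arr[i, j, ]
    mid <- (sp[1:(b - 2)] - 2 * sp[2:(b - 1)] + sp[3:b]) / h2
    out[i, j, ] <- c(mid[1], mid, mid[b - 2])
  }
  out
}

# staged reconstruction up to (and excluding) the median filter
o_recicg_prenorm <- function(arr, wavelengths, sigma = 4.44, window = c(790, 810)) {
  sm <- o_gauss_smooth(arr, sigma)
  d2 <- o_second_deriv(sm, wavelengths)
  keep <- which(wavelengths >= window[1] & wavelengths <= window[2])
  d <- dim(arr)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- mean(d2[i, j, keep])
    out[i, j] <- max(v, 0)
  }
  out
}

o_median_filter <- function(img, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(k * k)
    q <- 0L
    for (di in (-r):r) for (dj in (-r):r) {
      q <- q + 1L
      vals[q] <- img[o_reflect(i + di, nr), o_reflect(j + dj, nc)]
    }
    out[i, j] <- median(vals)
  }
  out
}

o_bilinear <- function(img, x, y) {
  x0 <- min(max(floor(x), 1), ncol(img) - 1L)
  y0 <- min(max(floor(y), 1), nrow(img) - 1L)
  fx <- x - x0; fy <- y - y0
  img[y0, x0] * (1 - fx) * (1 - fy) + img[y0, x0 + 1] * fx * (1 - fy) +
    img[y0 + 1, x0] * (1 - fx) * fy + img[y0 + 1, x0 + 1] * fx * fy
}

# mean over the inclusive disc by scanning every pixel
o_disc_mean <- function(mat, cx, cy, r) {
  acc <- 0; n <- 0L
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat))) {
    if ((j - cx)^2 + (i - cy)^2 <= r^2) { acc <- acc + mat[i, j]; n <- n + 1L }
  }
  acc / n
}

o_disc_count <- function(nr, nc, cx, cy, r) {
  n <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc))
    if ((j - cx)^2 + (i - cy)^2 <= r^2) n <- n + 1L
  n
}

o_movmean <- function(x, k) {
  if (k %% 2L == 0L) k <- k + 1L
  h <- (k - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    hw <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - hw):(i + hw)])
  }
  out
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
o_wilcox_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(rk[signs == 1L])
  }
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# rank-then-Pearson Spearman rho with mid-ranks
o_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# definition-based T0 scan: smallest sample index i >= i0 with the smoothed
# curve above B at every later sample, then raw confirmation
o_t0_scan <- function(curve, B, search_from_s = 6, noise_window_s = c(3, 6)) {
  t <- curve$t_s; s <- curve$smoothed; n <- length(t)
  i0 <- which(t >= search_from_s)[1]
  cand <- NA_integer_
  for (i in i0:n) if (all(s[i:n] > B)) { cand <- i; break }
  if (is.na(cand)) return(NA_real_)
  inw <- t >= noise_window_s[1] & t <= noise_window_s[2]
  B_raw <- max(B, curve$normalized[inw])
  for (i in cand:n) if (curve$normalized[i] > B_raw) return(t[i])
  NA_real_
}

# independent re-derivation of the slope segment rule (rle-based)
o_slope_rule <- function(curve, fraction = 0.5) {
  s <- curve$smoothed; t <- curve$t_s; n <- length(s)
  ds <- sapply(2:(n - 1), function(i) (s[i + 1] - s[i - 1]) / (t[i + 1] - t[i - 1]))
  mx <- max(ds); im <- which.max(ds)
  keep <- ds >= fraction * mx
  runs <- rle(keep)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  ri <- which(runs$values & starts <= im & ends >= im)
  seg <- (starts[ri]:ends[ri]) + 1L
  w <- curve$window_frames
  trim <- as.integer(ceiling(w / 2))
  if (length(seg) - 2L * trim >= 5L) seg <- seg[(trim + 1L):(length(seg) - trim)]
  if (length(seg) < 3L) seg <- max(1L, im):min(n, im + 2L)
  stats::coef(stats::lm(s[seg] ~ t[seg]))[[2]]
}

# exhaustive-scan chord/extremum-distance inflection with restricted pass
o_inflection <- function(pos, vals, smooth_window = 5L) {
  v <- o_movmean(vals, smooth_window)
  one_pass <- function(p, v) {
    n <- length(v)
    chord <- v[1] + (v[n] - v[1]) * (p - p[1]) / (p[n] - p[1])
    dev <- v - chord
    rng <- max(v) - min(v)
    if (rng <= 0 || max(abs(dev)) < 0.02 * rng) return(NA_real_)
    tol <- 0.05 * rng
    hi <- p[abs(dev - max(dev)) <= tol]
    lo <- p[abs(dev - min(dev)) <= tol]
    (mean(hi) + mean(lo)) / 2
  }
  est <- one_pass(pos, v)
  if (is.na(est)) return(NA_real_)
  span <- pos[length(pos)] - pos[1]
  keep <- which(pos >= est - span / 4 & pos <= est + span / 4)
  if (length(keep) >= 10L) {
    est2 <- one_pass(pos[keep], v[keep])
    if (!is.na(est2)) est <- est2
  }
  est
}

o_ttp_scan <- function(laser, t, hold_s = 1) {
  n <- length(laser)
  drops <- which(diff(laser) < -1e-9)
  start <- if (length(drops) == 0L) 1L else drops[1] + 1L
  for (i in start:n) {
    if (t[i] + hold_s > t[n]) break
    win <- which(t >= t[i] & t <= t[i] + hold_s)
    if (all(laser[win] >= laser[i] - 1e-9)) return(t[i])
  }
  NA_real_
}

# small random reflectance cube on the nominal grid
make_test_cube <- function(seed, h = 16L, w = 16L, b = 100L, tag = "intra") {
  set.seed(seed)
  arr <- array(runif(h * w * b, 0.2, 0.9), c(h, w, b))
  hs_cube(arr, seq(500, by = 5, length.out = b), tag)
}
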