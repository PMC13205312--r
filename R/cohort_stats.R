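# Cohort statistical layer: normality screening, paired nonparametric
# comparison of border distances between modalities, rank correlation of
# quantitative perfusion parameters, and retrospective power.

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, 3 <= n <= 5000, not constant.
#' @return list `(W, p)`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L)
    validation_error("Shapiro-Wilk requires 3 <= n <= 5000")
  if (max(x) == min(x)) degenerate_error("constant sample: normality test undefined")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired signed-rank test. Zero differences are dropped before
#' ranking (Wilcoxon's policy, the default) or kept in the ranking with
#' their signs discarded (`zero_policy = "pratt"`, normal approximation).
#' With the default policy the exact distribution is used for n <= 25
#' without ties, otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param a,b equal-length numeric vectors of paired observations.
#' @param zero_policy `"wilcoxon"` (drop zeros) or `"pratt"`.
#' @return list `(V, p, n_effective, method)`.
#' @export
wilcoxon_signed_rank <- function(a, b, zero_policy = c("wilcoxon", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) validation_error("paired samples must have equal length")
  d <- a - b
  if (any(!is.finite(d))) validation_error("paired differences must be finite")
  if (all(d == 0)) degenerate_error("all paired differences are zero")
  if (zero_policy == "wilcoxon") {
    dn <- d[d != 0]
    if (length(dn) < 3L)
      validation_error("fewer than 3 nonzero differences after dropping zeros")
    ties <- anyDuplicated(abs(dn)) > 0L
    exact <- length(dn) <= 25L && !ties
    ht <- suppressWarnings(stats::wilcox.test(dn, exact = exact, correct = !exact))
    list(V = unname(ht$statistic), p = ht$p.value, n_effective = length(dn),
         method = if (exact) "exact" else "normal approximation")
  } else {
    # Pratt: rank |d| including zeros, then drop the zero ranks
    r <- rank(abs(d))
    nz <- d != 0
    if (sum(nz) < 3L) validation_error("fewer than 3 nonzero differences")
    V <- sum(r[nz & d > 0])
    n <- length(d)
    n0 <- sum(!nz)
    mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
    tab <- table(r[nz])
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(tab^3 - tab) / 48
    z <- (V - mu) / sqrt(sig2)
    list(V = V, p = min(1, 2 * stats::pnorm(-abs(z))), n_effective = sum(nz),
         method = "pratt normal approximation")
  }
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks (ties averaged) with the t-distribution
#' approximation for the p-value.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list `(rho, p)`.
#' @export
spearman_rank <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4L)
    validation_error("Spearman correlation needs paired vectors of length >= 4")
  if (max(x) == min(x) || max(y) == min(y))
    degenerate_error("constant input: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Retrospective power of a paired comparison
#'
#' Power to detect a clinically relevant paired difference `delta_cm` at
#' two-sided level `alpha` with `n` pairs, given the observed standard
#' deviation of the paired differences. The effect size is
#' `d = delta_cm / sd_paired_diff` and power is computed for the paired
#' t-test from the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)`. `test = "wilcoxon"` applies the asymptotic
#' relative efficiency of the signed-rank test versus the t-test under
#' normality (0.955) as an effective sample-size factor.
#'
#' @param delta_cm clinically relevant difference (> 0), default 0.5 cm.
#' @param sd_paired_diff standard deviation of paired differences (> 0).
#' @param n number of pairs (>= 2).
#' @param alpha two-sided significance level, default 0.05.
#' @param test `"t"` (default) or `"wilcoxon"`.
#' @return power in (0, 1).
#' @export
retrospective_power <- function(delta_cm = 0.5, sd_paired_diff, n, alpha = 0.05,
                                test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (!is_scalar_number(delta_cm) || delta_cm <= 0)
    validation_error("delta_cm must be a positive scalar")
  if (!is_scalar_number(sd_paired_diff) || sd_paired_diff <= 0)
    validation_error("sd_paired_diff must be a positive scalar")
  if (!is_scalar_number(n) || n < 2) validation_error("n must be >= 2")
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1)
    validation_error("alpha must be in (0, 1)")
  n_eff <- if (test == "wilcoxon") 0.955 * n else n
  d <- delta_cm / sd_paired_diff
  df <- n_eff - 1
  ncp <- d * sqrt(n_eff)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Modality comparison report for a border-distance cohort
#'
#' Summarises signed border distances (cm to the clinical marker) per
#' modality over a cohort and tests each modality against a reference
#' modality with the paired Wilcoxon signed-rank test, annotated with the
#' retrospective power for the clinically relevant difference.
#'
#' Cases missing any modality are dropped (their count is reported);
#' at least 3 complete cases are required.
#'
#' @param distances data frame with columns `case`, `modality`,
#'   `distance_cm`.
#' @param reference modality name tested against (e.g. ground-truth ICG).
#' @param delta_cm clinically relevant difference for the power annotation.
#' @param alpha significance level.
#' @return list with `table` (data frame: `modality`, `n`, `median_cm`,
#'   and vs-reference `V`, `p`, `significant`, `sd_paired_diff`, `power`)
#'   and `n_dropped`.
#' @export
modality_comparison_report <- function(distances, reference, delta_cm = 0.5,
                                       alpha = 0.05) {
  need <- c("case", "modality", "distance_cm")
  if (!all(need %in% names(distances)))
    validation_error("distances needs columns case, modality, distance_cm")
  if (!reference %in% distances$modality)
    validation_error(sprintf("reference modality '%s' not present", reference))
  mods <- sort(unique(distances$modality))
  wide <- stats::reshape(distances[need], direction = "wide",
                         idvar = "case", timevar = "modality")
  names(wide) <- sub("^distance_cm\\.", "", names(wide))
  complete <- stats::complete.cases(wide[mods])
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("%d incomplete case(s) dropped", n_dropped))
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 3L)
    validation_error("fewer than 3 complete cases: cohort comparison not possible")
  rows <- lapply(mods, function(m) {
    out <- data.frame(modality = m, n = nrow(wide),
                      median_cm = stats::median(wide[[m]]),
                      V = NA_real_, p = NA_real_, significant = NA,
                      sd_paired_diff = NA_real_, power = NA_real_,
                      stringsAsFactors = FALSE)
    if (m != reference) {
      dd <- wide[[m]] - wide[[reference]]
      wt <- wilcoxon_signed_rank(wide[[m]], wide[[reference]])
      out$V <- wt$V; out$p <- wt$p; out$significant <- wt$p < alpha
      out$sd_paired_diff <- stats::sd(dd)
      if (out$sd_paired_diff > 0)
        out$power <- retrospective_power(delta_cm, out$sd_paired_diff,
                                         nrow(wide), alpha)
    }
    out
  })
  list(table = do.call(rbind, rows), n_dropped = n_dropped,
       reference = reference, delta_cm = delta_cm, alpha = alpha)
}
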