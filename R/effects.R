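#' Effect sizes of single and combined climate factors
#'
#' Single-factor and combined climate effects on growth are quantified
#' as the natural log response ratio (lnRR) of treatment vs ambient
#' control; the warming x precipitation interaction in each 2x2
#' scenario is quantified as a small-sample-corrected standardized
#' mean difference (Hedges' d). Both carry percentile bootstrap
#' confidence intervals; an effect is significant when its interval
#' excludes zero.
#'
#' @name effect_sizes
NULL

#' Natural log response ratio
#'
#' @param x_t response (growth rate) under treatment; must be positive.
#' @param x_c response under control; must be positive.
#' @return ln(x_t / x_c).
#' @export
ln_response_ratio <- function(x_t, x_c) {
  if (any(x_t <= 0) || any(x_c <= 0))
    stop("lnRR is defined for positive rates only")
  log(x_t / x_c)
}

#' Bootstrap lnRR of group means
#'
#' Point estimate is the lnRR of the observed group means; each
#' bootstrap draw resamples both groups with replacement and takes the
#' lnRR of the resampled means. Draws where a resampled mean is not
#' positive are rejected and redrawn (the ratio is undefined there); if
#' more than 10x `n_bootstrap` attempts are needed the comparison
#' errors out.
#'
#' @param treat per-replicate values under treatment.
#' @param control per-replicate values under control.
#' @param config a [qsip_config()].
#' @param seed optional seed overriding `config$rng_seed`.
#' @return one-row data.frame: `estimate`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
bootstrap_lnrr <- function(treat, control, config = qsip_config(),
                           seed = NULL) {
  stopifnot(length(treat) >= 2, length(control) >= 2)
  est <- ln_response_ratio(mean(treat), mean(control))
  set.seed(if (is.null(seed)) config$rng_seed + 2000L else seed)
  B <- config$n_bootstrap
  mt <- .boot_means(treat, B)
  mc <- .boot_means(control, B)
  tried <- B
  bad <- which(mt <= 0 | mc <= 0)
  while (length(bad)) {
    if (tried >= 10L * B)
      stop("bootstrap_lnrr: too many rejected draws (non-positive means)")
    mt[bad] <- .boot_means(treat, length(bad))
    mc[bad] <- .boot_means(control, length(bad))
    tried <- tried + length(bad)
    bad <- bad[mt[bad] <= 0 | mc[bad] <= 0]
  }
  draws <- log(mt / mc)
  ci <- .pct_ci(draws, config$ci_level)
  data.frame(estimate = est, ci_low = ci[1], ci_high = ci[2],
             significant = ci[1] > 0 || ci[2] < 0)
}

# B bootstrap means of one group (resampled with replacement)
.boot_means <- function(x, B) {
  n <- length(x)
  rowMeans(matrix(sample(x, B * n, replace = TRUE), nrow = B))
}

# B bootstrap d_I draws; degenerate draws (pooled sd 0) come back NaN/Inf
.boot_dI_draws <- function(values, B) {
  n <- vapply(values, length, 1L)
  J <- small_sample_correction(n[1], n[2], n[3], n[4])
  ms <- vs <- matrix(0, B, 4)
  for (g in 1:4) {
    mat <- matrix(sample(values[[g]], B * n[g], replace = TRUE), nrow = B)
    ms[, g] <- rowMeans(mat)
    vs[, g] <- rowSums((mat - ms[, g])^2) / (n[g] - 1)
  }
  s <- sqrt(as.vector(vs %*% (n - 1)) / (sum(n) - 4))
  ((ms[, 4] - ms[, 2]) - (ms[, 3] - ms[, 1])) / (2 * s) * J
}

#' Small-sample bias correction J(m) for Hedges' d
#'
#' @param n_c,n_a,n_b,n_ab group sample sizes.
#' @return the correction factor J = 1 - 3 / (4(m - 4) - 1) with
#'   m = n_c + n_a + n_b + n_ab.
#' @export
small_sample_correction <- function(n_c, n_a, n_b, n_ab) {
  m <- n_c + n_a + n_b + n_ab
  denom <- 4 * (m - 4) - 1
  if (denom <= 0) stop("too few samples for the Hedges correction")
  1 - 3 / denom
}

#' Pooled standard deviation of the four factorial groups
#'
#' @param values list of four numeric vectors (control, A, B, AB).
#' @return pooled sd.
#' @export
pooled_sd <- function(values) {
  stopifnot(length(values) == 4)
  n <- vapply(values, length, 1L)
  if (any(n < 2)) stop("each group needs >= 2 replicates for a pooled sd")
  v <- vapply(values, stats::var, 1)
  denom <- sum(n) - 4
  if (denom <= 0) stop("zero denominator in pooled sd")
  sqrt(sum((n - 1) * v) / denom)
}

#' Hedges' d interaction effect for a 2x2 factorial design
#'
#' d_I = [(mean_AB - mean_A) - (mean_B - mean_c)] / (2 s) * J(m),
#' where s is the pooled standard deviation. Zero under exact raw-scale
#' additivity; positive when the combined response exceeds the additive
#' expectation.
#'
#' @param values list of four per-replicate vectors, in order control,
#'   factor A, factor B, combined AB.
#' @return d_I point estimate.
#' @export
hedges_d_interaction <- function(values) {
  stopifnot(length(values) == 4)
  s <- pooled_sd(values)
  if (s == 0) stop("degenerate groups: pooled sd is zero")
  n <- vapply(values, length, 1L)
  m <- vapply(values, mean, 1)
  ((m[4] - m[2]) - (m[3] - m[1])) / (2 * s) *
    small_sample_correction(n[1], n[2], n[3], n[4])
}

#' Bootstrap Hedges' d_I
#'
#' Resamples within each of the four groups with replacement and
#' recomputes d_I per draw; degenerate draws (pooled sd zero) are
#' rejected and redrawn, bounded as in [bootstrap_lnrr()].
#'
#' @inheritParams hedges_d_interaction
#' @param config a [qsip_config()].
#' @param seed optional seed overriding `config$rng_seed`.
#' @return one-row data.frame: `estimate`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
bootstrap_dI <- function(values, config = qsip_config(), seed = NULL) {
  est <- hedges_d_interaction(values)
  set.seed(if (is.null(seed)) config$rng_seed + 3000L else seed)
  B <- config$n_bootstrap
  draws <- .boot_dI_draws(values, B)
  tried <- B
  bad <- which(!is.finite(draws))
  while (length(bad)) {
    if (tried >= 10L * B)
      stop("bootstrap_dI: too many degenerate draws (pooled sd zero)")
    draws[bad] <- .boot_dI_draws(values, length(bad))
    tried <- tried + length(bad)
    bad <- bad[!is.finite(draws[bad])]
  }
  ci <- .pct_ci(draws, config$ci_level)
  data.frame(estimate = est, ci_low = ci[1], ci_high = ci[2],
             significant = ci[1] > 0 || ci[2] < 0)
}
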