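hsVectors <- function(h) {
  stopifnot(is(h, "HarmonizedSet"))
  d <- harmonizedData(h)
  list(bx = d$beta_exposure, sx = d$se_exposure,
       by = d$beta_outcome, sy = d$se_outcome, id = d$snp_id)
}

# IVW fixed-effect slope: weighted LS of by on bx through the origin with
# weights 1/sy^2.  Written as the weighted mean of per-SNP ratios with the
# identical arithmetic used by mrIvw(), so subset re-estimates (MR-PRESSO's
# corrected beta) agree with mrIvw() bit for bit.
ivwSlope <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  sum(w * (by / bx)) / sum(w)
}

#' Wald ratio causal estimate for a single variant
#'
#' The per-SNP causal estimate is the outcome effect divided by the
#' exposure effect, `by / bx`, with the first-order delta-method standard
#' error `sy / |bx|` (exposure-side noise neglected, appropriate for
#' strong instruments).  Normal confidence interval and p-value.
#'
#' @param bx,by exposure and outcome per-allele effects.
#' @param sy outcome standard error.
#' @return An [MREstimate-class].
#' @export
waldRatio <- function(bx, by, sy) {
  if (bx == 0) stop("waldRatio: exposure effect is zero")
  stopifnot(sy > 0)
  newMREstimate("wald", beta = by / bx, se = sy / abs(bx), nSnp = 1L)
}

#' Inverse-variance weighted causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with weights `bx^2 / sy^2`,
#' algebraically the weighted least-squares slope of outcome on exposure
#' effects through the origin with weights `1 / sy^2`.  Cochran's Q over
#' the per-SNP ratios tests between-SNP heterogeneity (chi-square,
#' `n_snp - 1` df).  Under the default multiplicative-random-effects
#' model the standard error is inflated by `max(1, sqrt(Q / (n - 1)))`;
#' `model = "fixed"` leaves it untouched.  P-values are normal-based.
#'
#' @param h a [HarmonizedSet-class].
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return A list with elements `estimate` ([MREstimate-class]) and
#'   `heterogeneity` ([HeterogeneityResult-class], `NULL` for a single
#'   SNP).
#' @export
mrIvw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  v <- hsVectors(h)
  n <- length(v$bx)
  if (n == 0) stop("mrIvw: no SNPs")
  w <- v$bx^2 / v$sy^2
  theta <- v$by / v$bx
  beta <- sum(w * theta) / sum(w)
  se <- sqrt(1 / sum(w))
  het <- NULL
  if (n >= 2) {
    q <- sum(w * (theta - beta)^2)
    het <- new("HeterogeneityResult", q = q, df = n - 1L,
               pvalue = max(stats::pchisq(q, n - 1, lower.tail = FALSE),
                            .Machine$double.xmin))
    if (model == "multiplicative_random")
      se <- se * max(1, sqrt(q / (n - 1)))
  }
  method <- if (model == "fixed") "ivw_fixed" else "ivw_mre"
  list(estimate = newMREstimate(method, beta, se, n), heterogeneity = het)
}

#' MR-Egger regression
#'
#' Orients every SNP so the exposure effect is non-negative, then fits the
#' weighted linear regression `by = intercept + slope * bx` with weights
#' `1 / sy^2`.  The slope is the pleiotropy-adjusted causal estimate
#' (consistent under the InSIDE assumption); the intercept estimates the
#' average directional pleiotropy, and its test is the Egger intercept
#' test.  Standard errors use a multiplicative overdispersion factor
#' floored at 1, `max(1, sqrt(Q_egger / (n - 2)))`; p-values are from the
#' t distribution with `n - 2` df.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @return A list with elements `estimate` ([MREstimate-class]),
#'   `pleiotropy` ([PleiotropyResult-class]) and `heterogeneity`
#'   ([HeterogeneityResult-class], `n - 2` df).
#' @export
mrEgger <- function(h) {
  v <- hsVectors(h)
  n <- length(v$bx)
  if (n < 3) stop("mrEgger: needs at least 3 SNPs")
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (n - 2)))
  covU <- solve(xtwx)
  se <- sqrt(diag(covU)) * scale
  tint <- coefs[1] / se[1]
  est <- newMREstimate("egger", beta = coefs[2], se = se[2], nSnp = n,
                       df = n - 2L)
  plei <- new("PleiotropyResult", intercept = coefs[1], se = se[1],
              pvalue = max(2 * stats::pt(-abs(tint), n - 2),
                           .Machine$double.xmin))
  het <- new("HeterogeneityResult", q = q, df = n - 2L,
             pvalue = max(stats::pchisq(q, n - 2, lower.tail = FALSE),
                          .Machine$double.xmin))
  list(estimate = est, pleiotropy = plei, heterogeneity = het)
}

ratioWeights <- function(v) {
  w <- v$bx^2 / v$sy^2
  w / sum(w)
}

#' Weighted-median causal estimate
#'
#' The weighted 50th percentile of the per-SNP Wald ratios with weights
#' `bx^2 / sy^2` (normalized).  The quantile respects atoms: the smallest
#' ratio whose cumulative weight reaches one half is returned — so a SNP
#' carrying more than half the weight returns its own ratio, and equal
#' weights reduce to the plain median (adjacent ratios are averaged when
#' the cumulative weight lands on one half exactly).  Consistent when
#' valid instruments contribute a majority of the weight.  The standard
#' error is a parametric bootstrap: ratios are resampled from
#' `N(theta_j, se_theta_j^2)`, the weighted median recomputed, and the SD
#' taken; deterministic under `seed`.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MREstimate-class].
#' @export
weightedMedian <- function(h, n_boot = 1000, seed = 101) {
  v <- hsVectors(h)
  n <- length(v$bx)
  if (n < 3) stop("weightedMedian: needs at least 3 SNPs")
  theta <- v$by / v$bx
  se_theta <- v$sy / abs(v$bx)
  w <- ratioWeights(v)
  est <- weightedMedianAtom(theta, w)
  boots <- withr::with_seed(as.integer(seed), {
    draws <- matrix(stats::rnorm(n_boot * n, mean = theta, sd = se_theta),
                    nrow = n_boot, byrow = TRUE)
    apply(draws, 1, weightedMedianAtom, w = w)
  })
  se <- stats::sd(boots)
  if (se <= 0) se <- .Machine$double.eps
  newMREstimate("weighted_median", beta = est, se = se, nSnp = n)
}

modeFromRatios <- function(theta, w, bandwidth_factor) {
  sdw <- weightedSd(theta, w)
  madw <- weightedMad(theta, w)
  spread <- min(sdw, if (madw > 0) madw else sdw)
  if (!is.finite(spread) || spread <= 0)
    return(list(mode = theta[1], h = 0))
  bw <- bandwidth_factor * 0.9 * spread * length(theta)^(-1 / 5)
  d <- stats::density(theta, bw = bw, kernel = "gaussian",
                      weights = w / sum(w), n = 512,
                      from = min(theta) - 3 * bw, to = max(theta) + 3 * bw)
  list(mode = d$x[which.max(d$y)], h = bw)
}

#' Weighted-mode causal estimate
#'
#' The mode of the weighted kernel-smoothed density of per-SNP Wald
#' ratios (Gaussian kernel; bandwidth = `bandwidth_factor` times the
#' modified Silverman rule `0.9 min(sd_w, mad_w) n^{-1/5}` on the
#' weighted ratios; density maximized over a 512-point grid spanning the
#' ratios plus/minus three bandwidths, ties resolved to the lowest grid
#' point).  Consistent when the largest group of SNPs sharing a causal
#' estimate are valid instruments.  Bootstrap SE as in
#' [weightedMedian()].  When all ratios coincide the common ratio is
#' returned.
#'
#' @param h a [HarmonizedSet-class] with at least 3 SNPs.
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An [MREstimate-class].
#' @export
weightedMode <- function(h, bandwidth_factor = 1.0, n_boot = 1000,
                         seed = 101) {
  v <- hsVectors(h)
  n <- length(v$bx)
  if (n < 3) stop("weightedMode: needs at least 3 SNPs")
  theta <- v$by / v$bx
  se_theta <- v$sy / abs(v$bx)
  w <- ratioWeights(v)
  est <- modeFromRatios(theta, w, bandwidth_factor)$mode
  boots <- withr::with_seed(as.integer(seed), {
    draws <- matrix(stats::rnorm(n_boot * n, mean = theta, sd = se_theta),
                    nrow = n_boot, byrow = TRUE)
    apply(draws, 1, function(th)
      modeFromRatios(th, w, bandwidth_factor)$mode)
  })
  se <- stats::sd(boots)
  if (se <= 0) se <- .Machine$double.eps
  newMREstimate("weighted_mode", beta = est, se = se, nSnp = n)
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' `OR = exp(beta)` with the 95% Wald interval
#' `exp(beta +/- 1.96 se)`.
#'
#' @param beta causal log-odds estimate.
#' @param se its standard error (positive).
#' @return Named numeric vector `c(or, ci_low, ci_high)`.
#' @examples
#' round(toOddsRatio(-0.2244, 0.0589), 3)
#' @export
toOddsRatio <- function(beta, se) {
  stopifnot(se > 0)
  c(or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se))
}

#' Export per-SNP scatter data
#'
#' Writes the harmonized per-SNP effects (exposure and outcome betas and
#' SEs) used by the estimators — the content of an MR scatter plot.
#'
#' @param h a [HarmonizedSet-class].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
writeScatterData <- function(h, path) {
  d <- harmonizedData(h)
  utils::write.table(
    d[, c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
          "se_outcome")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
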