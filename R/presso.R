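# Leave-one-out IVW slopes for all SNPs at once.
looSlopes <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO: outlier detection and corrected estimation
#'
#' Residual-sum-of-squares based pleiotropy testing in three parts.
#' Global test: the observed weighted RSS, computed with leave-one-out
#' IVW slopes (`RSS = sum_j w_j (by_j - theta_{-j} bx_j)^2`,
#' `w_j = 1/sy_j^2`), is compared with its distribution over `n_sim`
#' simulated datasets drawn under the no-pleiotropy model
#' (`by*_j ~ N(theta_{-j} bx_j, sy_j^2)`, `bx*_j ~ N(bx_j, sx_j^2)`).
#' Outlier test: each SNP's observed residual contribution is compared
#' with its simulated distribution (two-sided empirical p, floored at
#' `1/(n_sim+1)`, Bonferroni-corrected across SNPs); SNPs with corrected
#' p below `outlier_alpha` are flagged.  Distortion test: the change in
#' the IVW estimate after removing the flagged SNPs is compared with the
#' change under removing equally many SNPs at random.  Deterministic
#' under `seed`.
#'
#' @param h a [HarmonizedSet-class] with at least 4 SNPs.
#' @param n_sim simulated datasets (default 1000).
#' @param outlier_alpha significance level for the Bonferroni-corrected
#'   per-SNP test (default 0.05).
#' @param seed RNG seed.
#' @return A [PressoResult-class].  `betaCorrected` is `NA` when no
#'   outliers are flagged, or withheld (with a warning) when fewer than 4
#'   SNPs would remain.
#' @export
mrPresso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 101) {
  v <- hsVectors(h)
  n <- length(v$bx)
  if (n < 4) stop("mrPresso: needs at least 4 SNPs")
  w <- 1 / v$sy^2
  theta_loo <- looSlopes(v$bx, v$by, w)
  contrib_obs <- w * (v$by - theta_loo * v$bx)^2
  rss_obs <- sum(contrib_obs)
  res <- withr::with_seed(as.integer(seed), {
    bx_sim <- matrix(stats::rnorm(n * n_sim, mean = v$bx, sd = v$sx),
                     nrow = n)
    by_sim <- matrix(stats::rnorm(n * n_sim, mean = theta_loo * v$bx,
                                  sd = v$sy), nrow = n)
    s1 <- colSums(w * bx_sim * by_sim)
    s2 <- colSums(w * bx_sim^2)
    theta_sim <- (rep(s1, each = n) - w * bx_sim * by_sim) /
      (rep(s2, each = n) - w * bx_sim^2)
    contrib_sim <- w * (by_sim - theta_sim * bx_sim)^2
    rss_sim <- colSums(contrib_sim)
    global_p <- max(mean(rss_sim >= rss_obs), 1 / (n_sim + 1))
    p_up <- rowMeans(contrib_sim >= contrib_obs)
    p_lo <- rowMeans(contrib_sim <= contrib_obs)
    p_two <- pmax(pmin(1, 2 * pmin(p_up, p_lo)), 1 / (n_sim + 1))
    p_bonf <- pmin(1, p_two * n)
    out_idx <- which(p_bonf < outlier_alpha)
    beta_raw <- ivwSlope(v$bx, v$by, v$sy)
    beta_corr <- NA_real_
    dist_p <- NA_real_
    if (length(out_idx)) {
      if (n - length(out_idx) <= 3) {
        warning("mrPresso: too few SNPs after outlier removal; ",
                "corrected estimate withheld")
      } else {
        keep <- setdiff(seq_len(n), out_idx)
        beta_corr <- ivwSlope(v$bx[keep], v$by[keep], v$sy[keep])
        d_obs <- beta_raw - beta_corr
        d_sim <- vapply(seq_len(n_sim), function(s) {
          drop <- sample.int(n, length(out_idx))
          keep_s <- setdiff(seq_len(n), drop)
          beta_raw - ivwSlope(v$bx[keep_s], v$by[keep_s], v$sy[keep_s])
        }, numeric(1))
        dist_p <- min(1, (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1))
      }
    }
    list(global_p = global_p, p_bonf = p_bonf, out_idx = out_idx,
         beta_raw = beta_raw, beta_corr = beta_corr, dist_p = dist_p)
  })
  new("PressoResult", rssObs = rss_obs, globalPvalue = res$global_p,
      perSnpPvalues = res$p_bonf, outlierIndices = as.integer(res$out_idx),
      betaRaw = res$beta_raw, betaCorrected = res$beta_corr,
      distortionPvalue = res$dist_p, nSim = as.integer(n_sim),
      seed = as.integer(seed))
}
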