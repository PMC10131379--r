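alignToFrame <- function(frame_row, trait_variants, policy, eaf_band) {
  j <- match(frame_row$snp_id, trait_variants$snp_id)
  if (is.na(j)) return(NULL)
  h <- harmonizePair(frame_row, trait_variants[j, , drop = FALSE],
                     policy = policy, eaf_band = eaf_band)
  if (h$status != "ok") return(NULL)
  h$outcome
}

#' Assemble a multivariable MR design from per-exposure instruments
#'
#' Takes the union of the per-exposure instrument sets, re-clumps it
#' jointly (the index SNP of each LD region is the one with the smallest
#' p-value across exposures, preventing double-counting of correlated
#' instruments), and aligns every exposure and the outcome onto a common
#' effect-allele frame.  SNPs absent from any exposure or from the
#' outcome, or excluded during harmonization, are dropped and logged.
#'
#' @param instrument_sets list of [InstrumentSet-class], one per exposure
#'   (same order as `exposures`).
#' @param exposures list of [GwasSummary-class] exposure datasets.
#' @param outcome a [GwasSummary-class].
#' @param ld an [LDMatrix-class] used for the joint re-clump.
#' @param params thresholds from [instrumentParams()].
#' @param policy,eaf_band harmonization policy (see [harmonizePair()]).
#' @return An [MVMRInput-class]; an error if fewer SNPs than exposures
#'   survive.
#' @export
assembleMvmrInput <- function(instrument_sets, exposures, outcome, ld,
                              params = instrumentParams(),
                              policy = c("exclude", "infer_by_eaf"),
                              eaf_band = c(0.42, 0.58)) {
  policy <- match.arg(policy)
  if (length(exposures) < 2) stop("MVMR needs at least 2 exposures")
  stopifnot(length(instrument_sets) == length(exposures))
  K <- length(exposures)
  enames <- vapply(exposures, function(g) g@traitName, character(1))
  cand <- do.call(rbind, lapply(instrument_sets, variants))
  # one row per unique SNP, carrying its smallest p across exposures
  cand <- cand[order(cand$pvalue), , drop = FALSE]
  cand <- cand[!duplicated(cand$snp_id), , drop = FALSE]
  kept <- clumpVariants(cand, ld, params$clump_r2, params$clump_window_kb)
  ov <- variants(outcome)
  rows <- vector("list", nrow(kept))
  dropped <- character()
  for (i in seq_len(nrow(kept))) {
    frame_row <- kept[i, , drop = FALSE]
    xb <- numeric(K); xs <- numeric(K)
    ok <- TRUE
    for (k in seq_len(K)) {
      al <- alignToFrame(frame_row, variants(exposures[[k]]), policy, eaf_band)
      if (is.null(al)) { ok <- FALSE; break }
      xb[k] <- al$beta; xs[k] <- al$se
    }
    if (ok) {
      alo <- alignToFrame(frame_row, ov, policy, eaf_band)
      if (is.null(alo)) ok <- FALSE
      else rows[[i]] <- list(id = frame_row$snp_id, xb = xb, xs = xs,
                             yb = alo$beta, ys = alo$se,
                             ea = frame_row$effect_allele,
                             oa = frame_row$other_allele,
                             eaf = frame_row$eaf)
    }
    if (!ok) dropped <- c(dropped, frame_row$snp_id)
  }
  if (length(dropped))
    message("assembleMvmrInput: dropped ", length(dropped),
            " SNP(s) missing or unharmonizable in some dataset")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  J <- length(rows)
  if (J <= K)
    stop("MVMR assembly left J = ", J, " SNPs for K = ", K, " exposures")
  ids <- vapply(rows, `[[`, character(1), "id")
  new("MVMRInput",
      snpIds = ids,
      exposureBetas = matrix(unlist(lapply(rows, `[[`, "xb")), nrow = J,
                             byrow = TRUE, dimnames = list(ids, enames)),
      exposureSes = matrix(unlist(lapply(rows, `[[`, "xs")), nrow = J,
                           byrow = TRUE, dimnames = list(ids, enames)),
      outcomeBeta = vapply(rows, `[[`, numeric(1), "yb"),
      outcomeSe = vapply(rows, `[[`, numeric(1), "ys"),
      exposureNames = enames,
      alleles = data.frame(
        snp_id = ids,
        effect_allele = vapply(rows, `[[`, character(1), "ea"),
        other_allele = vapply(rows, `[[`, character(1), "oa"),
        eaf = vapply(rows, `[[`, numeric(1), "eaf"),
        stringsAsFactors = FALSE))
}

#' Construct an MVMRInput directly from aligned matrices
#'
#' For simulation studies where effects are already on a common frame.
#'
#' @param exposure_betas,exposure_ses J x K matrices.
#' @param outcome_beta,outcome_se length-J vectors.
#' @param snp_ids optional instrument ids.
#' @param exposure_names optional exposure labels.
#' @param alleles optional allele-frame data.frame.
#' @return An [MVMRInput-class].
#' @export
MVMRInput <- function(exposure_betas, exposure_ses, outcome_beta,
                      outcome_se, snp_ids = NULL, exposure_names = NULL,
                      alleles = NULL) {
  exposure_betas <- as.matrix(exposure_betas)
  J <- nrow(exposure_betas); K <- ncol(exposure_betas)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%d", seq_len(J))
  if (is.null(exposure_names))
    exposure_names <- colnames(exposure_betas) %||% sprintf("exposure%d", seq_len(K))
  if (is.null(alleles))
    alleles <- data.frame(snp_id = snp_ids,
                          effect_allele = rep("A", J),
                          other_allele = rep("G", J),
                          eaf = rep(NA_real_, J), stringsAsFactors = FALSE)
  new("MVMRInput", snpIds = as.character(snp_ids),
      exposureBetas = exposure_betas, exposureSes = as.matrix(exposure_ses),
      outcomeBeta = as.numeric(outcome_beta),
      outcomeSe = as.numeric(outcome_se),
      exposureNames = as.character(exposure_names),
      alleles = alleles)
}

#' Multivariable IVW regression
#'
#' Weighted multivariable linear regression of the outcome effects on the
#' K exposure-effect columns with no intercept and weights
#' `1 / outcome_se^2`.  Each coefficient is the direct effect of that
#' exposure, holding the others fixed.  The coefficient covariance comes
#' from the weighted normal equations with a multiplicative
#' overdispersion factor `max(1, Q / (J - K))`; p-values use the t
#' distribution with `J - K` df.  A descriptive conditional
#' instrument-strength proxy is reported per exposure: the mean over SNPs
#' of `d_jk^2 / se_xjk^2`, where `d_jk` are the residuals of a weighted
#' regression of exposure k's effects on the other exposures' effects (no
#' threshold is enforced).
#'
#' @param m an [MVMRInput-class].
#' @return An [MVMREstimate-class].
#' @export
mvmrIvw <- function(m) {
  stopifnot(is(m, "MVMRInput"))
  validObject(m)
  X <- m@exposureBetas
  y <- m@outcomeBeta
  w <- 1 / m@outcomeSe^2
  J <- nrow(X); K <- ncol(X)
  xtwx <- crossprod(X, w * X)
  qrd <- qr(xtwx)
  if (qrd$rank < K) {
    stop("rank-deficient MVMR design; collinear exposure(s): ",
         paste(m@exposureNames[qrd$pivot[(qrd$rank + 1):K]], collapse = ", "))
  }
  coefs <- solve(xtwx, crossprod(X, w * y))
  resid <- y - X %*% coefs
  q <- sum(w * resid^2)
  phi <- max(1, q / (J - K))
  se <- sqrt(diag(solve(xtwx)) * phi)
  tval <- coefs / se
  pv <- pmax(2 * stats::pt(-abs(tval), J - K), .Machine$double.xmin)
  crit <- stats::qt(0.975, J - K)
  cond_f <- vapply(seq_len(K), function(k) {
    if (K == 1) return(mean(X[, 1]^2 / m@exposureSes[, 1]^2))
    Xo <- X[, -k, drop = FALSE]
    bh <- solve(crossprod(Xo, w * Xo), crossprod(Xo, w * X[, k]))
    d <- X[, k] - Xo %*% bh
    mean(d^2 / m@exposureSes[, k]^2)
  }, numeric(1))
  tab <- data.frame(
    exposure = m@exposureNames,
    beta = as.numeric(coefs), se = se,
    ci_low = as.numeric(coefs) - crit * se,
    ci_high = as.numeric(coefs) + crit * se,
    pvalue = as.numeric(pv),
    or = exp(as.numeric(coefs)),
    or_ci_low = exp(as.numeric(coefs) - crit * se),
    or_ci_high = exp(as.numeric(coefs) + crit * se),
    conditional_f = cond_f,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("MVMREstimate", table = tab, nSnp = as.integer(J), qStat = q)
}

#' Multivariable MR with additional covariate traits
#'
#' Extends an assembled [MVMRInput-class] with the effects of covariate
#' traits (e.g. lifestyle risk factors) at the same instruments: each
#' covariate's per-SNP effects are aligned to the input's allele frame
#' and appended as extra exposure columns, and the joint model is refit
#' with [mvmrIvw()].  SNPs missing from, or unharmonizable in, any
#' covariate are dropped with a log message.
#'
#' @param m an [MVMRInput-class].
#' @param covariate_exposures list of [GwasSummary-class] covariate
#'   datasets.
#' @param policy,eaf_band harmonization policy (see [harmonizePair()]).
#' @return An [MVMREstimate-class] over the extended exposure set.
#' @export
mvmrWithCovariates <- function(m, covariate_exposures,
                               policy = c("exclude", "infer_by_eaf"),
                               eaf_band = c(0.42, 0.58)) {
  stopifnot(is(m, "MVMRInput"))
  policy <- match.arg(policy)
  if (!length(covariate_exposures)) return(mvmrIvw(m))
  J <- length(m@snpIds)
  cov_names <- vapply(covariate_exposures, function(g) g@traitName,
                      character(1))
  cov_beta <- matrix(NA_real_, J, length(covariate_exposures),
                     dimnames = list(m@snpIds, cov_names))
  cov_se <- cov_beta
  frame <- m@alleles
  frame$beta <- 0; frame$se <- 1; frame$pvalue <- 1; frame$n <- 1
  frame$chrom <- "0"; frame$pos <- 0L
  for (c_i in seq_along(covariate_exposures)) {
    cv <- variants(covariate_exposures[[c_i]])
    for (j in seq_len(J)) {
      al <- alignToFrame(frame[j, , drop = FALSE], cv, policy, eaf_band)
      if (!is.null(al)) {
        cov_beta[j, c_i] <- al$beta
        cov_se[j, c_i] <- al$se
      }
    }
  }
  keep <- stats::complete.cases(cov_beta)
  if (!all(keep))
    message("mvmrWithCovariates: dropped ", sum(!keep),
            " SNP(s) missing in covariate dataset(s)")
  Kx <- ncol(m@exposureBetas) + ncol(cov_beta)
  if (sum(keep) <= Kx)
    stop("too few SNPs (J = ", sum(keep), ") for K = ", Kx,
         " exposures + covariates")
  m2 <- new("MVMRInput",
            snpIds = m@snpIds[keep],
            exposureBetas = cbind(m@exposureBetas[keep, , drop = FALSE],
                                  cov_beta[keep, , drop = FALSE]),
            exposureSes = cbind(m@exposureSes[keep, , drop = FALSE],
                                cov_se[keep, , drop = FALSE]),
            outcomeBeta = m@outcomeBeta[keep],
            outcomeSe = m@outcomeSe[keep],
            exposureNames = c(m@exposureNames, cov_names),
            alleles = m@alleles[keep, , drop = FALSE])
  mvmrIvw(m2)
}
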