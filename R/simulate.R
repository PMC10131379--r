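#' Configure the synthetic summary-statistics generator
#'
#' Builds a validated [SimulationConfig-class].  The generator emulates a
#' two-sample design: per-SNP effects gamma_j ~ N(gamma_mean, gamma_sd^2)
#' on a standardized quantitative exposure, and outcome effects on the
#' log-odds scale Gamma_j = causal_effect * gamma_j + alpha_j, where
#' alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2) is horizontal pleiotropy
#' (multiplied by `outlier_scale` for a random `outlier_fraction` of SNPs).
#' Observed effects add independent sampling noise with the standardized-
#' trait standard errors 1/sqrt(2 n_x f (1-f)) for the exposure and
#' 1/sqrt(2 f (1-f) n_eff), n_eff = n_cases n_controls / (n_cases +
#' n_controls), for the case-control outcome.
#'
#' @param n_snps number of variants (>= 3).
#' @param n_exposure exposure GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls outcome GWAS case/control
#'   counts.
#' @param causal_effect true causal log-odds per SD exposure.
#' @param gamma_mean,gamma_sd distribution of per-SNP exposure effects (SD
#'   units per allele).
#' @param pleiotropy_mean,pleiotropy_sd directional mean and spread of
#'   per-SNP pleiotropic outcome effects.
#' @param outlier_fraction fraction of SNPs whose pleiotropic effect is
#'   multiplied by `outlier_scale`.
#' @param outlier_scale outlier inflation multiplier.
#' @param eaf_range effect-allele frequencies are drawn uniformly from this
#'   range (within (0.01, 0.99)).
#' @param ld_block_size SNPs per LD block for [simulateLdBlockGwas()].
#' @param ld_within_block_r2 within-block r-squared.
#' @param palindromic_fraction fraction of SNPs assigned A/T or C/G allele
#'   pairs (exercises strand-ambiguity handling downstream).
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return A [SimulationConfig-class] object.
#' @export
simConfig <- function(n_snps = 100, n_exposure = 1e5,
                      n_outcome_cases = 2e4, n_outcome_controls = 2e4,
                      causal_effect = 0.2, gamma_mean = 0, gamma_sd = 0.05,
                      pleiotropy_mean = 0, pleiotropy_sd = 0,
                      outlier_fraction = 0, outlier_scale = 5,
                      eaf_range = c(0.05, 0.95), ld_block_size = 1,
                      ld_within_block_r2 = 0, palindromic_fraction = 0.1,
                      seed = 1) {
  new("SimulationConfig",
      nSnps = as.integer(n_snps), nExposure = as.numeric(n_exposure),
      nOutcomeCases = as.numeric(n_outcome_cases),
      nOutcomeControls = as.numeric(n_outcome_controls),
      causalEffect = as.numeric(causal_effect),
      gammaMean = as.numeric(gamma_mean), gammaSd = as.numeric(gamma_sd),
      pleiotropyMean = as.numeric(pleiotropy_mean),
      pleiotropySd = as.numeric(pleiotropy_sd),
      outlierFraction = as.numeric(outlier_fraction),
      outlierScale = as.numeric(outlier_scale),
      eafRange = as.numeric(eaf_range),
      ldBlockSize = as.integer(ld_block_size),
      ldWithinBlockR2 = as.numeric(ld_within_block_r2),
      palindromicFraction = as.numeric(palindromic_fraction),
      seed = as.integer(seed))
}

#' Read a generator configuration from a YAML file
#'
#' Keys match the arguments of [simConfig()].
#'
#' @param path YAML file path.
#' @return A [SimulationConfig-class] object.
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown simulation config key(s): ",
                        paste(bad, collapse = ", "))
  do.call(simConfig, vals)
}

NON_PALINDROMIC_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"), ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c(
  "A", "T", "T", "A", "C", "G", "G", "C"), ncol = 2, byrow = TRUE)

drawAlleles <- function(n, palindromic_fraction) {
  pal <- stats::runif(n) < palindromic_fraction
  idx_np <- sample.int(nrow(NON_PALINDROMIC_PAIRS), n, replace = TRUE)
  idx_p <- sample.int(nrow(PALINDROMIC_PAIRS), n, replace = TRUE)
  ea <- ifelse(pal, PALINDROMIC_PAIRS[idx_p, 1], NON_PALINDROMIC_PAIRS[idx_np, 1])
  oa <- ifelse(pal, PALINDROMIC_PAIRS[idx_p, 2], NON_PALINDROMIC_PAIRS[idx_np, 2])
  list(effect = ea, other = oa)
}

# SNPs placed so that no two correlated SNPs share a clump window; position
# slots cycle within the 32-bit range for very large panels (any SNPs that
# end up co-located are LD-free by construction, so clumping is unaffected).
spreadPositions <- function(n) {
  chrom <- as.character(((seq_len(n) - 1L) %% 22L) + 1L)
  slot <- (ceiling(seq_len(n) / 22) - 1L) %% 100L
  pos <- as.integer(1e6 + slot * 2e7)
  list(chrom = chrom, pos = pos)
}

waldP <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

variantTable <- function(snp_id, chrom, pos, alleles, eaf, beta, se, n) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = alleles$effect, other_allele = alleles$other,
             eaf = eaf, beta = beta, se = se, pvalue = waldP(beta, se),
             n = n, stringsAsFactors = FALSE)
}

#' Simulate a two-sample GWAS summary dataset with known truth
#'
#' Generates exposure and outcome summary statistics from the model in
#' [simConfig()], with independent sampling noise in the two samples and
#' a [TruthRecord-class] carrying the causal effect, per-SNP effects,
#' pleiotropy and planted outlier indices.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A list with elements `exposure` and `outcome`
#'   ([GwasSummary-class]) and `truth` ([TruthRecord-class]).
#' @examples
#' sim <- simulateTwoSample(simConfig(n_snps = 50, seed = 7))
#' sim$truth
#' @export
simulateTwoSample <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  withr::with_seed(cfg@seed, {
    n <- cfg@nSnps
    eaf <- stats::runif(n, cfg@eafRange[1], cfg@eafRange[2])
    gamma <- stats::rnorm(n, cfg@gammaMean, cfg@gammaSd)
    alpha <- stats::rnorm(n, cfg@pleiotropyMean, cfg@pleiotropySd)
    n_out <- floor(cfg@outlierFraction * n)
    out_idx <- if (n_out > 0) sort(sample.int(n, n_out)) else integer()
    if (n_out > 0) alpha[out_idx] <- alpha[out_idx] * cfg@outlierScale
    big_gamma <- cfg@causalEffect * gamma + alpha
    se_x <- 1 / sqrt(2 * cfg@nExposure * eaf * (1 - eaf))
    n_eff <- cfg@nOutcomeCases * cfg@nOutcomeControls /
      (cfg@nOutcomeCases + cfg@nOutcomeControls)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)
    bx <- stats::rnorm(n, gamma, se_x)
    by <- stats::rnorm(n, big_gamma, se_y)
    ids <- sprintf("rs%06d", seq_len(n))
    posn <- spreadPositions(n)
    al <- drawAlleles(n, cfg@palindromicFraction)
    exposure <- GwasSummary(
      variantTable(ids, posn$chrom, posn$pos, al, eaf, bx, se_x,
                   rep(cfg@nExposure, n)),
      traitName = "exposure", traitType = "quantitative",
      nTotal = cfg@nExposure)
    outcome <- GwasSummary(
      variantTable(ids, posn$chrom, posn$pos, al, eaf, by, se_y,
                   rep(cfg@nOutcomeCases + cfg@nOutcomeControls, n)),
      traitName = "outcome", traitType = "binary",
      nTotal = cfg@nOutcomeCases + cfg@nOutcomeControls,
      nCases = cfg@nOutcomeCases)
    truth <- new("TruthRecord", causalEffect = cfg@causalEffect,
                 perSnpGamma = matrix(gamma, ncol = 1,
                                      dimnames = list(ids, "exposure")),
                 perSnpAlpha = alpha, outlierIndices = as.integer(out_idx),
                 exposureCorrelation = matrix(1, 1, 1))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate an exposure GWAS with block LD structure
#'
#' Partitions SNPs into blocks of `ld_block_size`; each block sits on its
#' own chromosome with members 1 kb apart, sharing one underlying effect
#' plus a small jitter so p-values are distinct.  Within-block r-squared is
#' `ld_within_block_r2`, between-block r-squared is 0, so greedy clumping
#' at a threshold below the within-block value retains exactly one SNP per
#' block.
#'
#' @param cfg a [SimulationConfig-class] with `ld_block_size >= 2`.
#' @return A list with elements `gwas` ([GwasSummary-class]) and `ld`
#'   ([LDMatrix-class]).
#' @export
simulateLdBlockGwas <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  if (cfg@ldBlockSize < 2) stop("ld_block_size must be >= 2")
  withr::with_seed(cfg@seed, {
    n <- cfg@nSnps
    block <- rep(seq_len(ceiling(n / cfg@ldBlockSize)),
                 each = cfg@ldBlockSize)[seq_len(n)]
    n_blocks <- max(block)
    eaf <- stats::runif(n, cfg@eafRange[1], cfg@eafRange[2])
    base <- stats::rnorm(n_blocks, cfg@gammaMean, cfg@gammaSd)
    gamma <- base[block] + stats::rnorm(n, 0, 0.02 * max(cfg@gammaSd, 1e-6))
    se_x <- 1 / sqrt(2 * cfg@nExposure * eaf * (1 - eaf))
    bx <- stats::rnorm(n, gamma, se_x)
    ids <- sprintf("rs%06d", seq_len(n))
    chrom <- as.character(block)
    pos <- as.integer(1e6 + (seq_len(n) - (block - 1L) * cfg@ldBlockSize - 1L) * 1000L)
    al <- drawAlleles(n, cfg@palindromicFraction)
    gwas <- GwasSummary(
      variantTable(ids, chrom, pos, al, eaf, bx, se_x, rep(cfg@nExposure, n)),
      traitName = "exposure", traitType = "quantitative",
      nTotal = cfg@nExposure)
    r2 <- outer(block, block, function(a, b)
      ifelse(a == b, cfg@ldWithinBlockR2, 0))
    diag(r2) <- 1
    dimnames(r2) <- list(ids, ids)
    ld <- LDMatrix(r2, snpIds = ids,
                   positions = data.frame(snp_id = ids, chrom = chrom,
                                          pos = pos,
                                          stringsAsFactors = FALSE))
    list(gwas = gwas, ld = ld)
  })
}

#' Simulate correlated exposures for multivariable MR
#'
#' Draws per-SNP effect vectors on `k_exposures` exposures from a
#' multivariate normal with correlation `exposure_corr` (each marginal
#' N(gamma_mean, gamma_sd^2)); the outcome effect is the sum of direct
#' effects times per-exposure SNP effects plus a pleiotropic term.  Each
#' exposure GWAS receives independent sampling noise (separate samples).
#' This reproduces the classic univariable-vs-multivariable discrepancy:
#' an exposure with a null direct effect but strong correlation to a
#' causal exposure shows a nonzero univariable estimate.
#'
#' @param cfg a [SimulationConfig-class] (its `causal_effect` slot is
#'   ignored; `direct_effects` defines the truth).
#' @param k_exposures number of exposures.
#' @param direct_effects length-`k_exposures` vector of true direct
#'   effects.
#' @param exposure_corr positive-definite correlation matrix of per-SNP
#'   exposure effects (default identity).
#' @return A list with elements `exposures` (list of
#'   [GwasSummary-class]), `outcome` and `truth`.
#' @export
simulateMvmr <- function(cfg, k_exposures, direct_effects,
                         exposure_corr = diag(k_exposures)) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  k <- as.integer(k_exposures)
  if (length(direct_effects) != k)
    stop("direct_effects must have length k_exposures")
  exposure_corr <- as.matrix(exposure_corr)
  if (!isTRUE(all.equal(exposure_corr, t(exposure_corr))) ||
      !all(abs(diag(exposure_corr) - 1) < 1e-8))
    stop("exposure_corr must be a symmetric correlation matrix")
  ch <- tryCatch(chol(exposure_corr),
                 error = function(e) stop("exposure_corr is not positive-definite"))
  withr::with_seed(cfg@seed, {
    n <- cfg@nSnps
    eaf <- stats::runif(n, cfg@eafRange[1], cfg@eafRange[2])
    z <- matrix(stats::rnorm(n * k), n, k)
    gamma <- cfg@gammaMean + cfg@gammaSd * (z %*% ch)
    alpha <- stats::rnorm(n, cfg@pleiotropyMean, cfg@pleiotropySd)
    n_out <- floor(cfg@outlierFraction * n)
    out_idx <- if (n_out > 0) sort(sample.int(n, n_out)) else integer()
    if (n_out > 0) alpha[out_idx] <- alpha[out_idx] * cfg@outlierScale
    big_gamma <- as.numeric(gamma %*% direct_effects) + alpha
    se_x <- 1 / sqrt(2 * cfg@nExposure * eaf * (1 - eaf))
    n_eff <- cfg@nOutcomeCases * cfg@nOutcomeControls /
      (cfg@nOutcomeCases + cfg@nOutcomeControls)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * n_eff)
    ids <- sprintf("rs%06d", seq_len(n))
    posn <- spreadPositions(n)
    al <- drawAlleles(n, cfg@palindromicFraction)
    enames <- sprintf("exposure%d", seq_len(k))
    exposures <- lapply(seq_len(k), function(j) {
      bx <- stats::rnorm(n, gamma[, j], se_x)
      GwasSummary(
        variantTable(ids, posn$chrom, posn$pos, al, eaf, bx, se_x,
                     rep(cfg@nExposure, n)),
        traitName = enames[j], traitType = "quantitative",
        nTotal = cfg@nExposure)
    })
    names(exposures) <- enames
    by <- stats::rnorm(n, big_gamma, se_y)
    outcome <- GwasSummary(
      variantTable(ids, posn$chrom, posn$pos, al, eaf, by, se_y,
                   rep(cfg@nOutcomeCases + cfg@nOutcomeControls, n)),
      traitName = "outcome", traitType = "binary",
      nTotal = cfg@nOutcomeCases + cfg@nOutcomeControls,
      nCases = cfg@nOutcomeCases)
    dimnames(gamma) <- list(ids, enames)
    truth <- new("TruthRecord", causalEffect = as.numeric(direct_effects),
                 perSnpGamma = gamma, perSnpAlpha = alpha,
                 outlierIndices = as.integer(out_idx),
                 exposureCorrelation = exposure_corr)
    list(exposures = exposures, outcome = outcome, truth = truth)
  })
}
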