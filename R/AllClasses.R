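#' @import methods
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

GWAS_COLUMNS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue", "n")

#' GwasSummary: summary statistics for one trait
#'
#' Container for a trait's per-variant summary associations together with
#' trait-level metadata.  The variant table holds one row per SNP with the
#' canonical columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.  `beta` is the
#' per-effect-allele effect: SD units for a quantitative trait, log-odds for
#' a binary one.
#'
#' @slot traitName trait label.
#' @slot traitType `"quantitative"` or `"binary"`.
#' @slot nTotal total GWAS sample size.
#' @slot nCases number of cases (`NA` for quantitative traits).
#' @slot variants data.frame of per-variant associations.
#' @slot nDropped rows dropped on ingest for failing validation.
#'
#' @aliases GwasSummary-class
#' @exportClass GwasSummary
setClass("GwasSummary",
  representation(
    traitName = "character",
    traitType = "character",
    nTotal = "numeric",
    nCases = "numeric",
    variants = "data.frame",
    nDropped = "numeric"
  ),
  prototype(
    traitName = "trait", traitType = "quantitative",
    nTotal = NA_real_, nCases = NA_real_, nDropped = 0
  )
)

validVariantRows <- function(v) {
  ok <- rep(TRUE, nrow(v))
  ok <- ok & !is.na(v$snp_id) & nzchar(v$snp_id)
  ok <- ok & v$effect_allele %in% VALID_ALLELES & v$other_allele %in% VALID_ALLELES
  ok <- ok & !is.na(v$effect_allele) & !is.na(v$other_allele) &
    v$effect_allele != v$other_allele
  ok <- ok & !is.na(v$eaf) & v$eaf >= 0 & v$eaf <= 1
  ok <- ok & !is.na(v$beta) & is.finite(v$beta)
  ok <- ok & !is.na(v$se) & v$se > 0
  ok <- ok & !is.na(v$pvalue) & v$pvalue > 0 & v$pvalue <= 1
  ok <- ok & !is.na(v$n) & v$n > 0
  ok <- ok & !is.na(v$pos)
  ok
}

setValidity("GwasSummary", function(object) {
  msg <- character()
  v <- object@variants
  missing_cols <- setdiff(GWAS_COLUMNS, names(v))
  if (length(missing_cols))
    return(paste("variants lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(v$snp_id))
    msg <- c(msg, "duplicated snp_id in variants")
  if (!object@traitType %in% c("quantitative", "binary"))
    msg <- c(msg, "traitType must be 'quantitative' or 'binary'")
  if (identical(object@traitType, "binary")) {
    if (is.na(object@nCases))
      msg <- c(msg, "binary trait requires nCases")
    else if (!is.na(object@nTotal) && object@nCases >= object@nTotal)
      msg <- c(msg, "nCases must be < nTotal")
  }
  if (nrow(v) && !all(validVariantRows(v)))
    msg <- c(msg, "variants contains rows violating field invariants")
  if (length(msg)) msg else TRUE
})

#' Construct a GwasSummary
#'
#' @param variants data.frame with the canonical summary-statistics columns.
#' @param traitName trait label.
#' @param traitType `"quantitative"` or `"binary"`.
#' @param nTotal total sample size; defaults to the maximum per-SNP `n`.
#' @param nCases case count for binary traits.
#' @param nDropped rows dropped upstream (bookkeeping).
#' @return A [GwasSummary-class] object.
#' @export
GwasSummary <- function(variants, traitName = "trait",
                        traitType = c("quantitative", "binary"),
                        nTotal = NA_real_, nCases = NA_real_, nDropped = 0) {
  traitType <- match.arg(traitType)
  variants <- as.data.frame(variants)[, GWAS_COLUMNS, drop = FALSE]
  rownames(variants) <- NULL
  if (is.na(nTotal) && nrow(variants)) nTotal <- max(variants$n)
  new("GwasSummary", traitName = traitName, traitType = traitType,
      nTotal = as.numeric(nTotal), nCases = as.numeric(nCases),
      variants = variants, nDropped = as.numeric(nDropped))
}

#' LDMatrix: pairwise squared-correlation structure
#'
#' Symmetric matrix of r-squared values between variants, with unit diagonal.
#' Pairs absent from the source data default to r-squared 0.
#'
#' @slot snpIds variant identifiers (row/column order of `r2`).
#' @slot r2 symmetric numeric matrix in \[0, 1\].
#' @slot positions optional data.frame (snp_id, chrom, pos); may be empty.
#'
#' @aliases LDMatrix-class
#' @exportClass LDMatrix
setClass("LDMatrix",
  representation(snpIds = "character", r2 = "matrix", positions = "data.frame"),
  prototype(positions = data.frame(snp_id = character(), chrom = character(),
                                   pos = numeric()))
)

setValidity("LDMatrix", function(object) {
  m <- object@r2
  n <- length(object@snpIds)
  if (!is.numeric(m) || nrow(m) != n || ncol(m) != n)
    return("r2 must be a numeric matrix conformable with snpIds")
  if (n == 0) return(TRUE)
  if (anyDuplicated(object@snpIds)) return("duplicated snp ids")
  if (any(abs(diag(m) - 1) > 1e-8)) return("diagonal entries must equal 1")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("r2 entries must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) return("r2 matrix must be symmetric")
  TRUE
})

#' Construct an LDMatrix
#'
#' @param r2 square symmetric matrix of r-squared values; dimnames are used
#'   as snp ids when `snpIds` is missing.
#' @param snpIds variant identifiers.
#' @param positions optional data.frame (snp_id, chrom, pos).
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(r2, snpIds = rownames(r2), positions = NULL) {
  r2 <- as.matrix(r2)
  dimnames(r2) <- list(snpIds, snpIds)
  if (is.null(positions))
    positions <- data.frame(snp_id = character(), chrom = character(),
                            pos = numeric())
  new("LDMatrix", snpIds = as.character(snpIds), r2 = r2,
      positions = as.data.frame(positions))
}

#' InstrumentSet: selected instrumental variants for one exposure
#'
#' Output of the instrument-selection pipeline: the surviving exposure
#' variants, per-SNP variance explained, the F-statistic strength metrics,
#' and per-SNP provenance flags (which QC stages each variant passed, and
#' the outcome variant it was matched to, possibly a proxy).
#'
#' @slot variants data.frame of exposure associations for the retained SNPs.
#' @slot perSnpR2 per-SNP variance explained (2 b^2 f (1-f)).
#' @slot totalR2 sum of `perSnpR2`.
#' @slot meanF mean of per-SNP F statistics (k = 1).
#' @slot jointF F statistic from `totalR2` with k = number of SNPs.
#' @slot provenance data.frame of per-SNP QC flags and outcome mapping.
#' @slot exposureN exposure GWAS sample size used for F.
#'
#' @aliases InstrumentSet-class
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  representation(
    variants = "data.frame", perSnpR2 = "numeric", totalR2 = "numeric",
    meanF = "numeric", jointF = "numeric", provenance = "data.frame",
    exposureN = "numeric"
  )
)

setValidity("InstrumentSet", function(object) {
  k <- nrow(object@variants)
  if (length(object@perSnpR2) != k) return("perSnpR2 length must equal #snps")
  if (any(object@perSnpR2 < 0)) return("perSnpR2 must be non-negative")
  if (abs(object@totalR2 - sum(object@perSnpR2)) > 1e-8 * max(1, object@totalR2))
    return("totalR2 must equal sum(perSnpR2)")
  TRUE
})

#' HarmonizedSet: exposure/outcome effects on a common allele frame
#'
#' Per-SNP exposure and outcome effects expressed for the same effect
#' allele, after resolving swapped and strand-flipped alleles and applying
#' the palindromic-SNP policy.  Excluded SNPs are absent from the data and
#' recorded in the exclusion log.
#'
#' @slot data data.frame with columns snp_id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, eaf_exposure, flags.
#' @slot exclusions data.frame (snp_id, reason) for dropped SNPs.
#'
#' @aliases HarmonizedSet-class
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
  representation(data = "data.frame", exclusions = "data.frame"),
  prototype(exclusions = data.frame(snp_id = character(), reason = character()))
)

setValidity("HarmonizedSet", function(object) {
  need <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome",
            "se_outcome", "eaf_exposure", "flags")
  if (!all(need %in% names(object@data)))
    return("data lacks required harmonized columns")
  d <- object@data
  if (nrow(d)) {
    if (any(d$se_exposure <= 0) || any(d$se_outcome <= 0))
      return("standard errors must be positive")
    if (anyDuplicated(d$snp_id)) return("duplicated snp_id")
  }
  TRUE
})

#' Construct a HarmonizedSet from aligned effect vectors
#'
#' @param snp_id,beta_exposure,se_exposure,beta_outcome,se_outcome,eaf_exposure
#'   equal-length per-SNP vectors, already on a common effect-allele frame.
#' @param flags optional per-SNP flag strings (semicolon-separated).
#' @param exclusions optional data.frame (snp_id, reason).
#' @return A [HarmonizedSet-class] object.
#' @export
HarmonizedSet <- function(snp_id, beta_exposure, se_exposure, beta_outcome,
                          se_outcome, eaf_exposure = rep(NA_real_, length(snp_id)),
                          flags = rep("", length(snp_id)),
                          exclusions = NULL) {
  d <- data.frame(snp_id = as.character(snp_id),
                  beta_exposure = beta_exposure, se_exposure = se_exposure,
                  beta_outcome = beta_outcome, se_outcome = se_outcome,
                  eaf_exposure = eaf_exposure, flags = flags,
                  stringsAsFactors = FALSE)
  if (is.null(exclusions))
    exclusions <- data.frame(snp_id = character(), reason = character())
  new("HarmonizedSet", data = d, exclusions = as.data.frame(exclusions))
}

#' MREstimate: one method's causal estimate
#'
#' A causal effect on the log-odds-per-SD-exposure scale with its standard
#' error, 95% confidence interval, p-value, and the exponentiated
#' odds-ratio scale.
#'
#' @slot method estimator label.
#' @slot beta causal log-OR per SD exposure.
#' @slot se standard error.
#' @slot ciLow,ciHigh 95% confidence bounds (log scale).
#' @slot pvalue two-sided p-value.
#' @slot orValue,orCiLow,orCiHigh odds-ratio scale.
#' @slot nSnp number of instruments used.
#'
#' @aliases MREstimate-class
#' @exportClass MREstimate
setClass("MREstimate",
  representation(
    method = "character", beta = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric", pvalue = "numeric",
    orValue = "numeric", orCiLow = "numeric", orCiHigh = "numeric",
    nSnp = "integer"
  )
)

setValidity("MREstimate", function(object) {
  if (object@se <= 0) return("se must be positive")
  if (object@ciLow >= object@ciHigh) return("ciLow must be < ciHigh")
  if (object@pvalue <= 0 || object@pvalue > 1) return("pvalue must be in (0,1]")
  if (abs(object@orValue - exp(object@beta)) > 1e-8 * object@orValue)
    return("orValue must equal exp(beta)")
  TRUE
})

newMREstimate <- function(method, beta, se, nSnp, pvalue = NULL,
                          df = NULL) {
  z <- beta / se
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
              else 2 * stats::pt(-abs(z), df)
  }
  pvalue <- max(pvalue, .Machine$double.xmin)
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  lo <- beta - crit * se
  hi <- beta + crit * se
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = lo, ciHigh = hi, pvalue = pvalue,
      orValue = exp(beta), orCiLow = exp(lo), orCiHigh = exp(hi),
      nSnp = as.integer(nSnp))
}

#' HeterogeneityResult: Cochran's Q over per-SNP causal estimates
#'
#' @slot q Q statistic.
#' @slot df degrees of freedom (n_snp - 1 for IVW, n_snp - 2 for Egger).
#' @slot pvalue upper-tail chi-square p-value.
#' @aliases HeterogeneityResult-class
#' @exportClass HeterogeneityResult
setClass("HeterogeneityResult",
  representation(q = "numeric", df = "integer", pvalue = "numeric"))

#' PleiotropyResult: MR-Egger intercept test
#'
#' @slot intercept estimated average directional pleiotropy.
#' @slot se its standard error.
#' @slot pvalue two-sided t-test p-value.
#' @aliases PleiotropyResult-class
#' @exportClass PleiotropyResult
setClass("PleiotropyResult",
  representation(intercept = "numeric", se = "numeric", pvalue = "numeric"))

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot rssObs observed weighted residual sum of squares.
#' @slot globalPvalue empirical global-test p-value.
#' @slot perSnpPvalues Bonferroni-corrected per-SNP outlier p-values.
#' @slot outlierIndices indices of flagged SNPs.
#' @slot betaRaw IVW estimate on all SNPs.
#' @slot betaCorrected IVW estimate with outliers removed (`NA` if none or
#'   withheld for too few remaining SNPs).
#' @slot distortionPvalue empirical distortion-test p-value (`NA` if no
#'   outliers).
#' @slot nSim number of simulated datasets.
#' @slot seed RNG seed used.
#' @aliases PressoResult-class
#' @exportClass PressoResult
setClass("PressoResult",
  representation(
    rssObs = "numeric", globalPvalue = "numeric", perSnpPvalues = "numeric",
    outlierIndices = "integer", betaRaw = "numeric", betaCorrected = "numeric",
    distortionPvalue = "numeric", nSim = "integer", seed = "integer"
  )
)

setValidity("PressoResult", function(object) {
  n <- length(object@perSnpPvalues)
  if (length(object@outlierIndices) &&
      (min(object@outlierIndices) < 1 || max(object@outlierIndices) > n))
    return("outlierIndices out of range")
  if (object@rssObs < 0) return("rssObs must be non-negative")
  TRUE
})

#' SimulationConfig: parameters of the synthetic summary-data generator
#'
#' Defines a two-sample design: per-SNP effects on an exposure, outcome
#' effects on the log-odds scale composed of a causal part plus a
#' pleiotropic part, sampling noise scaled by sample size and allele
#' frequency, optional LD blocks and planted outliers.
#'
#' @slot nSnps number of variants.
#' @slot nExposure exposure GWAS sample size.
#' @slot nOutcomeCases,nOutcomeControls outcome GWAS case/control counts.
#' @slot causalEffect true causal log-odds per SD exposure.
#' @slot gammaMean,gammaSd normal distribution of per-SNP exposure effects.
#' @slot pleiotropyMean,pleiotropySd mean/SD of per-SNP direct outcome
#'   effects (horizontal pleiotropy).
#' @slot outlierFraction fraction of SNPs whose pleiotropic effect is
#'   inflated.
#' @slot outlierScale multiplier applied to outlier pleiotropic effects.
#' @slot eafRange range of effect-allele frequencies.
#' @slot ldBlockSize SNPs per LD block (1 = independent SNPs).
#' @slot ldWithinBlockR2 within-block r-squared.
#' @slot palindromicFraction fraction of SNPs given A/T or C/G alleles.
#' @slot seed RNG seed.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nSnps = "integer", nExposure = "numeric", nOutcomeCases = "numeric",
    nOutcomeControls = "numeric", causalEffect = "numeric",
    gammaMean = "numeric", gammaSd = "numeric",
    pleiotropyMean = "numeric", pleiotropySd = "numeric",
    outlierFraction = "numeric", outlierScale = "numeric",
    eafRange = "numeric", ldBlockSize = "integer",
    ldWithinBlockR2 = "numeric", palindromicFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSnps < 3) msg <- c(msg, "nSnps must be >= 3")
  if (object@nExposure <= 0 || object@nOutcomeCases <= 0 ||
      object@nOutcomeControls <= 0)
    msg <- c(msg, "sample sizes must be positive")
  if (length(object@eafRange) != 2 || object@eafRange[1] >= object@eafRange[2] ||
      object@eafRange[1] < 0.01 || object@eafRange[2] > 0.99)
    msg <- c(msg, "eafRange must be an increasing pair within (0.01, 0.99)")
  if (object@outlierFraction < 0 || object@outlierFraction >= 1)
    msg <- c(msg, "outlierFraction must be in [0, 1)")
  if (object@ldWithinBlockR2 < 0 || object@ldWithinBlockR2 >= 1)
    msg <- c(msg, "ldWithinBlockR2 must be in [0, 1)")
  if (object@ldBlockSize < 1) msg <- c(msg, "ldBlockSize must be >= 1")
  if (object@palindromicFraction < 0 || object@palindromicFraction > 1)
    msg <- c(msg, "palindromicFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TruthRecord: ground truth of a synthetic dataset
#'
#' @slot causalEffect true causal effect(s); a vector of direct effects in
#'   multivariable scenarios.
#' @slot perSnpGamma per-SNP exposure effects (matrix with one column per
#'   exposure).
#' @slot perSnpAlpha per-SNP pleiotropic outcome effects.
#' @slot outlierIndices indices of SNPs with inflated pleiotropy.
#' @slot exposureCorrelation exposure-effect correlation matrix.
#' @aliases TruthRecord-class
#' @exportClass TruthRecord
setClass("TruthRecord",
  representation(
    causalEffect = "numeric", perSnpGamma = "matrix",
    perSnpAlpha = "numeric", outlierIndices = "integer",
    exposureCorrelation = "matrix"
  )
)

#' MVMRInput: multivariable MR design
#'
#' Per-SNP effects of J instruments on K exposures plus the outcome, on a
#' common effect-allele frame.  The allele frame (effect/other allele per
#' SNP) is retained so covariate traits can be aligned later.
#'
#' @slot snpIds instrument identifiers (length J).
#' @slot exposureBetas,exposureSes J x K matrices.
#' @slot outcomeBeta,outcomeSe length-J vectors.
#' @slot exposureNames K exposure labels.
#' @slot alleles data.frame (snp_id, effect_allele, other_allele, eaf)
#'   defining the common frame.
#' @aliases MVMRInput-class
#' @exportClass MVMRInput
setClass("MVMRInput",
  representation(
    snpIds = "character", exposureBetas = "matrix", exposureSes = "matrix",
    outcomeBeta = "numeric", outcomeSe = "numeric",
    exposureNames = "character", alleles = "data.frame"
  )
)

setValidity("MVMRInput", function(object) {
  J <- length(object@snpIds)
  K <- length(object@exposureNames)
  if (nrow(object@exposureBetas) != J || ncol(object@exposureBetas) != K)
    return("exposureBetas must be J x K")
  if (!identical(dim(object@exposureBetas), dim(object@exposureSes)))
    return("exposureSes must match exposureBetas")
  if (length(object@outcomeBeta) != J || length(object@outcomeSe) != J)
    return("outcome vectors must have length J")
  if (J <= K) return("need more SNPs than exposures (J > K)")
  if (any(object@outcomeSe <= 0)) return("outcome SEs must be positive")
  TRUE
})

#' MVMREstimate: joint direct effects from multivariable MR
#'
#' @slot table data.frame with one row per exposure: beta, se, ci, p-value
#'   and odds-ratio scale, plus the conditional instrument-strength proxy.
#' @slot nSnp number of instruments J.
#' @slot qStat overdispersion (weighted residual sum of squares).
#' @aliases MVMREstimate-class
#' @exportClass MVMREstimate
setClass("MVMREstimate",
  representation(table = "data.frame", nSnp = "integer", qStat = "numeric"))

#' StudyConfig: layout of a full MR study grid
#'
#' @slot exposures,outcomes lists of trait entries; each entry is a list
#'   with `name` and either `file` (a summary-statistics TSV) or `data`
#'   (a [GwasSummary-class]), plus optional `trait_type`, `n_total`,
#'   `n_cases`.
#' @slot ldSource path to an LD table, or an [LDMatrix-class].
#' @slot thresholds instrument-selection parameters (p_threshold, clump_r2,
#'   clump_window_kb, maf_min, proxy_r2).
#' @slot policies harmonization parameters (palindromic_policy, eaf_band).
#' @slot methods enabled estimators.
#' @slot fdrAlpha FDR significance level.
#' @slot seed master seed; all stage seeds derive from it.
#' @slot outputDir directory for result tables ("" = do not write).
#' @aliases StudyConfig-class
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    exposures = "list", outcomes = "list", ldSource = "ANY",
    thresholds = "list", policies = "list", methods = "character",
    fdrAlpha = "numeric", seed = "integer", outputDir = "character"
  )
)

setValidity("StudyConfig", function(object) {
  if (!length(object@exposures)) return("need at least one exposure")
  if (!length(object@outcomes)) return("need at least one outcome")
  if (object@fdrAlpha <= 0 || object@fdrAlpha >= 1)
    return("fdrAlpha must be in (0, 1)")
  TRUE
})
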