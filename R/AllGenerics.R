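#' Accessors for mrflow classes
#'
#' Small accessor family: `variants()` returns the per-variant table of a
#' [GwasSummary-class] or [InstrumentSet-class]; `snpIds()` the variant
#' identifiers; `nVariants()` their count; `r2Matrix()` the squared-
#' correlation matrix of an [LDMatrix-class]; `harmonizedData()` and
#' `exclusions()` the aligned effect table and exclusion log of a
#' [HarmonizedSet-class]; `meanF()` and `totalR2()` the instrument-strength
#' metrics of an [InstrumentSet-class]; `outliers()` the flagged indices of
#' a [PressoResult-class]; `estimateTable()` the per-exposure table of an
#' [MVMREstimate-class].
#'
#' @param x an mrflow object.
#' @return The slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("r2Matrix", function(x) standardGeneric("r2Matrix"))
#' @rdname accessors
#' @export
setGeneric("harmonizedData", function(x) standardGeneric("harmonizedData"))
#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))
#' @rdname accessors
#' @export
setGeneric("meanF", function(x) standardGeneric("meanF"))
#' @rdname accessors
#' @export
setGeneric("totalR2", function(x) standardGeneric("totalR2"))
#' @rdname accessors
#' @export
setGeneric("outliers", function(x) standardGeneric("outliers"))
#' @rdname accessors
#' @export
setGeneric("estimateTable", function(x) standardGeneric("estimateTable"))

#' @rdname accessors
setMethod("variants", "GwasSummary", function(x) x@variants)
#' @rdname accessors
setMethod("variants", "InstrumentSet", function(x) x@variants)
#' @rdname accessors
setMethod("snpIds", "GwasSummary", function(x) x@variants$snp_id)
#' @rdname accessors
setMethod("snpIds", "InstrumentSet", function(x) x@variants$snp_id)
#' @rdname accessors
setMethod("snpIds", "LDMatrix", function(x) x@snpIds)
#' @rdname accessors
setMethod("snpIds", "HarmonizedSet", function(x) x@data$snp_id)
#' @rdname accessors
setMethod("snpIds", "MVMRInput", function(x) x@snpIds)
#' @rdname accessors
setMethod("nVariants", "GwasSummary", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("nVariants", "InstrumentSet", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("nVariants", "HarmonizedSet", function(x) nrow(x@data))
#' @rdname accessors
setMethod("r2Matrix", "LDMatrix", function(x) x@r2)
#' @rdname accessors
setMethod("harmonizedData", "HarmonizedSet", function(x) x@data)
#' @rdname accessors
setMethod("exclusions", "HarmonizedSet", function(x) x@exclusions)
#' @rdname accessors
setMethod("meanF", "InstrumentSet", function(x) x@meanF)
#' @rdname accessors
setMethod("totalR2", "InstrumentSet", function(x) x@totalR2)
#' @rdname accessors
setMethod("outliers", "PressoResult", function(x) x@outlierIndices)
#' @rdname accessors
setMethod("estimateTable", "MVMREstimate", function(x) x@table)

setMethod("show", "GwasSummary", function(object) {
  cat("GwasSummary:", object@traitName,
      sprintf("(%s)", object@traitType), "\n")
  cat("  variants:", nrow(object@variants),
      " n_total:", object@nTotal, "\n")
  if (!is.na(object@nCases)) cat("  n_cases:", object@nCases, "\n")
  if (object@nDropped > 0) cat("  rows dropped on ingest:", object@nDropped, "\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix:", length(object@snpIds), "variants\n")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet:", nrow(object@variants), "instruments\n")
  cat(sprintf("  total R2 = %.4g, mean F = %.1f, joint F = %.1f\n",
              object@totalR2, object@meanF, object@jointF))
  if (any(object@provenance$proxy_used))
    cat("  proxies used:", sum(object@provenance$proxy_used), "\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", nrow(object@data), "SNPs harmonized,",
      nrow(object@exclusions), "excluded\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s], %d SNPs\n", object@method, object@nSnp))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pvalue))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f)\n",
              object@orValue, object@orCiLow, object@orCiHigh))
})

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              object@q, object@df, object@pvalue))
})

setMethod("show", "PleiotropyResult", function(object) {
  cat(sprintf("Egger intercept = %.4g (se %.4g), p = %.3g\n",
              object@intercept, object@se, object@pvalue))
})

setMethod("show", "PressoResult", function(object) {
  cat("MR-PRESSO:", sprintf("RSS = %.4g, global p = %.4g\n",
                            object@rssObs, object@globalPvalue))
  if (length(object@outlierIndices)) {
    cat("  outliers:", paste(object@outlierIndices, collapse = ", "), "\n")
    cat(sprintf("  beta raw = %.4f, corrected = %.4f, distortion p = %.3g\n",
                object@betaRaw, object@betaCorrected,
                object@distortionPvalue))
  } else {
    cat("  no outliers detected; beta =", sprintf("%.4f", object@betaRaw), "\n")
  }
})

setMethod("show", "MVMREstimate", function(object) {
  cat("MVMREstimate:", nrow(object@table), "exposures,",
      object@nSnp, "SNPs\n")
  print(object@table, digits = 4)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSnps, "SNPs, causal effect",
      object@causalEffect, "\n")
  cat(sprintf("  exposure n = %g, outcome %g/%g (cases/controls)\n",
              object@nExposure, object@nOutcomeCases, object@nOutcomeControls))
  cat(sprintf("  pleiotropy N(%g, %g^2), outliers %g%% x%g, seed %d\n",
              object@pleiotropyMean, object@pleiotropySd,
              100 * object@outlierFraction, object@outlierScale, object@seed))
})

setMethod("show", "TruthRecord", function(object) {
  cat("TruthRecord: causal effect(s)",
      paste(signif(object@causalEffect, 4), collapse = ", "), "\n")
  cat("  SNPs:", nrow(object@perSnpGamma),
      " outliers:", length(object@outlierIndices), "\n")
})

setMethod("show", "StudyConfig", function(object) {
  cat("StudyConfig:", length(object@exposures), "exposures x",
      length(object@outcomes), "outcomes; methods:",
      paste(object@methods, collapse = ", "), "\n")
})
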