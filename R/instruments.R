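#' Default instrument-selection thresholds
#'
#' Genome-wide significance 5e-8 (strict `<`), clump r-squared 0.01 with a
#' 10,000 kb window, minor-allele-frequency floor 1% (kept when MAF >= 1%),
#' and proxy lookup at r-squared strictly greater than 0.8.
#'
#' @param p_threshold genome-wide significance threshold.
#' @param clump_r2 LD pruning threshold.
#' @param clump_window_kb total clump window in kb (a candidate is inside
#'   the window of an index SNP when on the same chromosome within half the
#'   window on either side).
#' @param maf_min minimum minor-allele frequency.
#' @param proxy_r2 minimum (strict) r-squared for a proxy variant.
#' @return A named list of thresholds.
#' @export
instrumentParams <- function(p_threshold = 5e-8, clump_r2 = 0.01,
                             clump_window_kb = 10000, maf_min = 0.01,
                             proxy_r2 = 0.8) {
  list(p_threshold = p_threshold, clump_r2 = clump_r2,
       clump_window_kb = clump_window_kb, maf_min = maf_min,
       proxy_r2 = proxy_r2)
}

#' Select genome-wide significant variants
#'
#' Keeps exactly the variants with `pvalue < p_threshold` (strict
#' inequality).
#'
#' @param g a [GwasSummary-class].
#' @param p_threshold significance threshold (default 5e-8).
#' @return data.frame of the selected variant rows.
#' @export
selectGenomeWide <- function(g, p_threshold = 5e-8) {
  stopifnot(is(g, "GwasSummary"))
  v <- variants(g)
  out <- v[v$pvalue < p_threshold, , drop = FALSE]
  if (nrow(out) == 0)
    message("selectGenomeWide: no variant reaches p < ", p_threshold)
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping of candidate variants
#'
#' Sorts candidates by ascending p-value and repeatedly promotes the best
#' remaining variant to index SNP, removing all remaining variants on the
#' same chromosome within half the window on either side whose r-squared
#' with the index reaches `r2_threshold`.  Among correlated pairs the
#' lower-p variant is always the one retained.  Pairs absent from `ld`
#' count as r-squared 0.
#'
#' @param candidates data.frame of variant rows (needs `snp_id`, `chrom`,
#'   `pos`, `pvalue`).
#' @param ld an [LDMatrix-class].
#' @param r2_threshold prune when r-squared >= this value (default 0.01).
#' @param window_kb total window size in kb (default 10,000).
#' @return data.frame of index variants in selection order.
#' @export
clumpVariants <- function(candidates, ld, r2_threshold = 0.01,
                          window_kb = 10000) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0) return(candidates)
  if (any(is.na(candidates$pos)) || any(is.na(candidates$chrom))) {
    no_pos <- candidates$snp_id[is.na(candidates$pos) | is.na(candidates$chrom)]
    unknown <- setdiff(no_pos, snpIds(ld))
    if (length(unknown))
      stop("cannot assess LD for candidate(s) without position or LD entry: ",
           paste(unknown, collapse = ", "))
  }
  half_window_bp <- window_kb * 1000 / 2
  remaining <- candidates[order(candidates$pvalue, candidates$snp_id), ,
                          drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  ids <- snpIds(ld)
  while (nrow(remaining) > 0) {
    index <- remaining[1, , drop = FALSE]
    kept <- rbind(kept, index)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    in_window <- remaining$chrom == index$chrom &
      abs(remaining$pos - index$pos) <= half_window_bp
    ii <- match(index$snp_id, ids)
    r2 <- if (is.na(ii)) rep(0, nrow(remaining)) else {
      jj <- match(remaining$snp_id, ids)
      r <- rep(0, nrow(remaining))
      r[!is.na(jj)] <- ld@r2[ii, jj[!is.na(jj)]]
      r
    }
    remaining <- remaining[!(in_window & r2 >= r2_threshold), , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

#' Filter variants by minor-allele frequency
#'
#' Keeps variants with `min(eaf, 1 - eaf) >= maf_min`; the boundary MAF
#' equal to `maf_min` is kept (the exclusion rule is MAF < 1%).
#'
#' @param candidates data.frame of variant rows with `eaf`.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @return data.frame of surviving rows.
#' @export
filterMaf <- function(candidates, maf_min = 0.01) {
  candidates <- as.data.frame(candidates)
  maf <- pmin(candidates$eaf, 1 - candidates$eaf)
  out <- candidates[maf >= maf_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find a proxy variant in the outcome GWAS
#'
#' For a variant absent from the outcome GWAS, returns the outcome variant
#' with the largest r-squared to it, provided that r-squared exceeds
#' `r2_min` strictly; ties are broken by smaller p-value, then
#' lexicographic snp id.  Returns `NULL` when no qualifying variant exists
#' or the requested id is unknown to the LD matrix (with a warning).
#'
#' @param snp_id the requested variant id.
#' @param outcome a [GwasSummary-class].
#' @param ld an [LDMatrix-class].
#' @param r2_min strict lower bound on proxy r-squared (default 0.8).
#' @return A single-row data.frame (the proxy's outcome record) or `NULL`.
#' @export
findProxy <- function(snp_id, outcome, ld, r2_min = 0.8) {
  ids <- snpIds(ld)
  ii <- match(snp_id, ids)
  if (is.na(ii)) {
    warning("findProxy: ", snp_id, " unknown to the LD matrix")
    return(NULL)
  }
  ov <- variants(outcome)
  jj <- match(ov$snp_id, ids)
  r2 <- rep(0, nrow(ov))
  r2[!is.na(jj)] <- ld@r2[ii, jj[!is.na(jj)]]
  r2[ov$snp_id == snp_id] <- 0  # the variant itself is not a proxy
  elig <- which(r2 > r2_min)
  if (!length(elig)) return(NULL)
  ord <- elig[order(-r2[elig], ov$pvalue[elig], ov$snp_id[elig])]
  out <- ov[ord[1], , drop = FALSE]
  attr(out, "proxy_r2") <- r2[ord[1]]
  rownames(out) <- NULL
  out
}

#' Variance in the exposure explained by one variant
#'
#' For a standardized trait, a variant with per-allele effect `beta` and
#' effect-allele frequency `eaf` explains `2 * beta^2 * eaf * (1 - eaf)`
#' of the trait variance.
#'
#' @param beta per-allele effect (SD units).
#' @param eaf effect-allele frequency in \[0, 1\].
#' @return Variance explained (vectorized).
#' @export
varianceExplained <- function(beta, eaf) {
  stopifnot(all(eaf >= 0 & eaf <= 1))
  2 * beta^2 * eaf * (1 - eaf)
}

#' Instrument-strength F statistic
#'
#' `F = R2 (n - k - 1) / (k (1 - R2))` for `k` instruments jointly
#' explaining a fraction `R2` of the exposure variance in a GWAS of `n`
#' individuals.  A mean F above 10 is the conventional bound for suitable
#' instruments.
#'
#' @param r2_total variance explained, in \[0, 1).
#' @param n exposure GWAS sample size (must exceed k + 1).
#' @param k number of instruments (>= 1).
#' @return The F statistic (vectorized over `r2_total`).
#' @export
fStatistic <- function(r2_total, n, k) {
  if (any(r2_total < 0) || any(r2_total >= 1))
    stop("r2_total must lie in [0, 1)")
  if (k < 1) stop("k must be >= 1")
  if (n <= k + 1) stop("n must exceed k + 1")
  r2_total * (n - k - 1) / (k * (1 - r2_total))
}

#' Build an instrument set with the full quality-control cascade
#'
#' Applies, in order: genome-wide significance filtering, greedy LD
#' clumping, minor-allele-frequency filtering, and outcome matching with
#' proxy fallback for variants absent from the outcome GWAS.  A proxy is
#' only accepted when its effect-allele frequency orientation is
#' unambiguous (|eaf_proxy - eaf_request| < 0.2); proxy use is flagged in
#' the provenance table.  Per-SNP variance explained, total R2, the mean
#' of per-SNP F statistics (k = 1) and the joint F are computed; a mean F
#' at or below 10 triggers a weak-instrument warning.
#'
#' @param exposure,outcome [GwasSummary-class] objects.
#' @param ld an [LDMatrix-class].
#' @param params thresholds from [instrumentParams()].
#' @return An [InstrumentSet-class].
#' @export
buildInstrumentSet <- function(exposure, outcome, ld,
                               params = instrumentParams()) {
  stopifnot(is(exposure, "GwasSummary"), is(outcome, "GwasSummary"),
            is(ld, "LDMatrix"))
  gw <- selectGenomeWide(exposure, params$p_threshold)
  if (nrow(gw) == 0) stop("no instruments: nothing genome-wide significant")
  cl <- clumpVariants(gw, ld, params$clump_r2, params$clump_window_kb)
  mf <- filterMaf(cl, params$maf_min)
  if (nrow(mf) == 0) stop("no instruments survive clumping + MAF filtering")
  ov <- variants(outcome)
  keep <- logical(nrow(mf))
  proxy_used <- logical(nrow(mf))
  outcome_snp <- character(nrow(mf))
  for (i in seq_len(nrow(mf))) {
    id <- mf$snp_id[i]
    if (id %in% ov$snp_id) {
      keep[i] <- TRUE
      outcome_snp[i] <- id
    } else {
      px <- suppressWarnings(findProxy(id, outcome, ld, params$proxy_r2))
      if (!is.null(px) && abs(px$eaf - mf$eaf[i]) < 0.2) {
        keep[i] <- TRUE
        proxy_used[i] <- TRUE
        outcome_snp[i] <- px$snp_id
        message("buildInstrumentSet: using proxy ", px$snp_id, " for ", id)
      } else {
        message("buildInstrumentSet: no outcome match or proxy for ", id)
      }
    }
  }
  v <- mf[keep, , drop = FALSE]
  if (nrow(v) == 0) stop("no instruments matched to the outcome GWAS")
  rownames(v) <- NULL
  per_r2 <- varianceExplained(v$beta, v$eaf)
  per_f <- vapply(seq_len(nrow(v)), function(i)
    fStatistic(per_r2[i], v$n[i], 1L), numeric(1))
  total_r2 <- sum(per_r2)
  n_exp <- if (!is.na(exposure@nTotal)) exposure@nTotal else max(v$n)
  joint_f <- if (total_r2 < 1 && n_exp > nrow(v) + 1)
    fStatistic(total_r2, n_exp, nrow(v)) else NA_real_
  mean_f <- mean(per_f)
  if (mean_f <= 10)
    warning("weak instruments: mean F = ", signif(mean_f, 4), " (<= 10)")
  prov <- data.frame(snp_id = v$snp_id, genome_wide = TRUE,
                     clump_kept = TRUE, maf_pass = TRUE,
                     proxy_used = proxy_used[keep],
                     outcome_snp_id = outcome_snp[keep],
                     stringsAsFactors = FALSE)
  new("InstrumentSet", variants = v, perSnpR2 = per_r2,
      totalR2 = total_r2, meanF = mean_f, jointF = joint_f,
      provenance = prov, exposureN = n_exp)
}
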