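#' Is an allele pair palindromic?
#'
#' A variant is palindromic (strand-ambiguous) when its two alleles are
#' complementary: A/T or C/G.
#'
#' @param a1,a2 single-character alleles among A, C, G, T (vectorized).
#' @return Logical vector.
#' @export
isPalindromic <- function(a1, a2) {
  stopifnot(all(a1 %in% VALID_ALLELES), all(a2 %in% VALID_ALLELES))
  complementAllele(a1) == a2
}

#' Harmonize one exposure/outcome variant pair
#'
#' Places the outcome association on the exposure's effect-allele frame.
#' Identical alleles pass through; swapped alleles negate the outcome beta
#' and complement its frequency (flag `allele_flipped`); alleles matching
#' only after strand complement are complemented first and then treated
#' the same way.  Palindromic variants cannot be resolved from allele
#' labels: under `policy = "exclude"` they are dropped; under
#' `"infer_by_eaf"` orientation is taken from effect-allele-frequency
#' agreement unless either frequency falls inside the ambiguity band, in
#' which case the variant is dropped.  Allele sets that do not match even
#' after complementing are dropped as ambiguous.
#'
#' @param exp,out single-row variant data.frames (same snp id, or a
#'   proxy-mapped pair — see `proxy`).
#' @param policy `"exclude"` (default) or `"infer_by_eaf"`.
#' @param eaf_band ambiguity band for frequency-based inference.
#' @param proxy set `TRUE` when `out` is a proxy variant for `exp`; allele
#'   labels are then not comparable and orientation is taken from the
#'   (pre-checked) frequency agreement.
#' @return A list with elements `status` (`"ok"` or `"excluded"`),
#'   `reason` (when excluded), `flags` (character vector), `exposure` and
#'   `outcome` (the aligned rows; outcome alleles rewritten to the
#'   exposure frame).
#' @export
harmonizePair <- function(exp, out, policy = c("exclude", "infer_by_eaf"),
                          eaf_band = c(0.42, 0.58), proxy = FALSE) {
  policy <- match.arg(policy)
  exp <- as.data.frame(exp)
  out <- as.data.frame(out)
  if (!proxy && exp$snp_id != out$snp_id)
    stop("harmonizePair: snp_id mismatch (", exp$snp_id, " vs ", out$snp_id, ")")
  flags <- character()
  excl <- function(reason) list(status = "excluded", reason = reason,
                                flags = flags, exposure = exp, outcome = out)
  flip <- function(o) {
    o$beta <- -o$beta
    o$eaf <- 1 - o$eaf
    o
  }
  toFrame <- function(o) {
    o$effect_allele <- exp$effect_allele
    o$other_allele <- exp$other_allele
    o
  }
  if (proxy) {
    # orientation by frequency agreement; checked upstream at |diff| < 0.2
    flags <- c(flags, "proxy_used")
    return(list(status = "ok", reason = NA_character_, flags = flags,
                exposure = exp, outcome = toFrame(out)))
  }
  pal <- isPalindromic(exp$effect_allele, exp$other_allele)
  ea <- exp$effect_allele; oa <- exp$other_allele
  if (pal) {
    flags <- c(flags, "palindromic")
    if (!all(c(out$effect_allele, out$other_allele) %in% c(ea, oa)))
      return(excl("excluded_ambiguous"))
    if (policy == "exclude") return(excl("palindromic_excluded"))
    inBand <- function(f) f > eaf_band[1] & f < eaf_band[2]
    if (inBand(exp$eaf) || inBand(out$eaf))
      return(excl("palindromic_eaf_ambiguous"))
    flags <- c(flags, "palindromic_inferred")
    aligned <- (exp$eaf < 0.5) == (out$eaf < 0.5)
    o <- if (aligned) out else {
      flags <- c(flags, "allele_flipped")
      flip(out)
    }
    return(list(status = "ok", reason = NA_character_, flags = flags,
                exposure = exp, outcome = toFrame(o)))
  }
  oe <- out$effect_allele; oo <- out$other_allele
  if (oe == ea && oo == oa) {
    o <- out
  } else if (oe == oa && oo == ea) {
    flags <- c(flags, "allele_flipped")
    o <- flip(out)
  } else if (complementAllele(oe) == ea && complementAllele(oo) == oa) {
    o <- out
  } else if (complementAllele(oe) == oa && complementAllele(oo) == ea) {
    flags <- c(flags, "allele_flipped")
    o <- flip(out)
  } else {
    return(excl("excluded_ambiguous"))
  }
  list(status = "ok", reason = NA_character_, flags = flags,
       exposure = exp, outcome = toFrame(o))
}

harmonizeCore <- function(exp_rows, out_lookup, policy, eaf_band,
                          proxy_flags = NULL, outcome_ids = NULL) {
  n <- nrow(exp_rows)
  if (is.null(outcome_ids)) outcome_ids <- exp_rows$snp_id
  if (is.null(proxy_flags)) proxy_flags <- rep(FALSE, n)
  rec <- vector("list", n)
  excl <- list()
  for (i in seq_len(n)) {
    oid <- outcome_ids[i]
    j <- match(oid, out_lookup$snp_id)
    if (is.na(j)) {
      excl[[length(excl) + 1]] <- data.frame(
        snp_id = exp_rows$snp_id[i], reason = "absent_from_outcome",
        stringsAsFactors = FALSE)
      next
    }
    h <- harmonizePair(exp_rows[i, , drop = FALSE],
                       out_lookup[j, , drop = FALSE],
                       policy = policy, eaf_band = eaf_band,
                       proxy = proxy_flags[i])
    if (h$status == "excluded") {
      excl[[length(excl) + 1]] <- data.frame(
        snp_id = exp_rows$snp_id[i], reason = h$reason,
        stringsAsFactors = FALSE)
    } else {
      rec[[i]] <- data.frame(
        snp_id = exp_rows$snp_id[i],
        beta_exposure = h$exposure$beta, se_exposure = h$exposure$se,
        beta_outcome = h$outcome$beta, se_outcome = h$outcome$se,
        eaf_exposure = h$exposure$eaf,
        flags = paste(h$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  ex <- if (length(excl)) do.call(rbind, excl)
        else data.frame(snp_id = character(), reason = character())
  list(data = d, exclusions = ex)
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' Applies [harmonizePair()] to every instrument, using the outcome
#' mapping recorded by [buildInstrumentSet()] (proxies included); excluded
#' variants are logged with reasons, and the result is ordered by snp id.
#'
#' @param instruments an [InstrumentSet-class].
#' @param outcome a [GwasSummary-class].
#' @param policy,eaf_band see [harmonizePair()].
#' @return A [HarmonizedSet-class]; an error if every SNP is excluded.
#' @export
harmonizeAll <- function(instruments, outcome,
                         policy = c("exclude", "infer_by_eaf"),
                         eaf_band = c(0.42, 0.58)) {
  stopifnot(is(instruments, "InstrumentSet"), is(outcome, "GwasSummary"))
  policy <- match.arg(policy)
  if (nVariants(instruments) == 0) stop("empty instrument set")
  prov <- instruments@provenance
  res <- harmonizeCore(variants(instruments), variants(outcome),
                       policy, eaf_band,
                       proxy_flags = prov$proxy_used,
                       outcome_ids = prov$outcome_snp_id)
  if (is.null(res$data) || nrow(res$data) == 0)
    stop("harmonizeAll: all SNPs excluded during harmonization")
  d <- res$data[order(res$data$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  new("HarmonizedSet", data = d, exclusions = res$exclusions)
}

#' Harmonize the shared variants of two summary datasets
#'
#' Convenience wrapper that aligns every SNP present in both files without
#' instrument-selection filtering — useful for simulation studies where
#' the instrument list is known.
#'
#' @param exposure,outcome [GwasSummary-class] objects.
#' @param policy,eaf_band see [harmonizePair()].
#' @return A [HarmonizedSet-class].
#' @export
harmonizeSummaries <- function(exposure, outcome,
                               policy = c("exclude", "infer_by_eaf"),
                               eaf_band = c(0.42, 0.58)) {
  policy <- match.arg(policy)
  ev <- variants(exposure)
  shared <- ev$snp_id[ev$snp_id %in% variants(outcome)$snp_id]
  if (!length(shared)) stop("no shared variants to harmonize")
  res <- harmonizeCore(ev[match(shared, ev$snp_id), , drop = FALSE],
                       variants(outcome), policy, eaf_band)
  if (is.null(res$data) || nrow(res$data) == 0)
    stop("harmonizeSummaries: all SNPs excluded during harmonization")
  d <- res$data[order(res$data$snp_id), , drop = FALSE]
  rownames(d) <- NULL
  new("HarmonizedSet", data = d, exclusions = res$exclusions)
}

#' Write a harmonization exclusion log
#'
#' @param h a [HarmonizedSet-class].
#' @param path output TSV path (columns snp_id, reason).
#' @return Invisibly, `path`.
#' @export
writeExclusions <- function(h, path) {
  utils::write.table(exclusions(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
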