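#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1, returned in input
#' order.  Delegates to [stats::p.adjust()] after validating the domain.
#'
#' @param pvalues numeric vector with entries in (0, 1].
#' @return q-values in input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.04))
#' @export
benjaminiHochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Configure a full MR study grid
#'
#' @param exposures,outcomes lists of trait entries; each a list with
#'   `name` and either `file` (summary-statistics TSV readable by
#'   [readGwas()]) or `data` (a [GwasSummary-class]), plus optional
#'   `trait_type`, `n_total`, `n_cases`.
#' @param ld an [LDMatrix-class] or a path readable by [readLdMatrix()].
#' @param thresholds instrument thresholds ([instrumentParams()]).
#' @param policies list with `palindromic_policy` and `eaf_band`.
#' @param methods estimators to run; any of `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"mrpresso"`.
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir directory for result files; `""` disables writing.
#' @return A [StudyConfig-class].
#' @export
studyConfig <- function(exposures, outcomes, ld,
                        thresholds = instrumentParams(),
                        policies = list(palindromic_policy = "exclude",
                                        eaf_band = c(0.42, 0.58)),
                        methods = c("ivw", "egger", "weighted_median",
                                    "weighted_mode", "mrpresso"),
                        fdr_alpha = 0.05, seed = 1, output_dir = "") {
  new("StudyConfig", exposures = exposures, outcomes = outcomes,
      ldSource = ld, thresholds = thresholds, policies = policies,
      methods = methods, fdrAlpha = fdr_alpha, seed = as.integer(seed),
      outputDir = output_dir)
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [studyConfig()]: `exposures`
#' and `outcomes` (lists of `name`/`file` entries), `ld` (a file path),
#' `thresholds`, `policies`, `methods`, `fdr_alpha`, `seed`,
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return A [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  thr <- do.call(instrumentParams, vals$thresholds %||% list())
  pol <- list(palindromic_policy = vals$policies$palindromic_policy %||% "exclude",
              eaf_band = unlist(vals$policies$eaf_band) %||% c(0.42, 0.58))
  studyConfig(exposures = vals$exposures, outcomes = vals$outcomes,
              ld = vals$ld,
              thresholds = thr, policies = pol,
              methods = unlist(vals$methods) %||%
                c("ivw", "egger", "weighted_median", "weighted_mode",
                  "mrpresso"),
              fdr_alpha = vals$fdr_alpha %||% 0.05,
              seed = vals$seed %||% 1,
              output_dir = vals$output_dir %||% "")
}

loadTrait <- function(entry, default_type) {
  g <- if (!is.null(entry$data)) entry$data
       else readGwas(entry$file,
                     trait_type = entry$trait_type %||% default_type,
                     n_total = entry$n_total %||% NA_real_,
                     n_cases = entry$n_cases %||% NA_real_)
  if (!is.null(entry$name)) g@traitName <- entry$name
  g
}

loadLd <- function(src) {
  if (is(src, "LDMatrix")) src else readLdMatrix(src)
}

estimateRow <- function(exposure, outcome, est, extra = list()) {
  data.frame(exposure = exposure, outcome = outcome, method = est@method,
             n_snp = est@nSnp, beta = est@beta, se = est@se,
             or = est@orValue, or_ci_low = est@orCiLow,
             or_ci_high = est@orCiHigh, pvalue = est@pvalue,
             q_stat = extra$q %||% NA_real_, q_pvalue = extra$qp %||% NA_real_,
             egger_intercept_p = extra$eip %||% NA_real_,
             mean_f = extra$mean_f %||% NA_real_,
             flags = extra$flags %||% "",
             stringsAsFactors = FALSE)
}

numFmt <- function(d) {
  for (col in names(d)) if (is.numeric(d[[col]]))
    d[[col]] <- formatC(d[[col]], digits = 10, format = "g")
  d
}

#' Run the univariable MR study grid
#'
#' For every exposure-outcome pair: builds instruments, harmonizes,
#' runs the enabled estimators with heterogeneity (Cochran's Q), the
#' Egger intercept test, and MR-PRESSO; then applies Benjamini-Hochberg
#' FDR within each (outcome, method) family across exposures.  Pairs
#' that fail (e.g. zero surviving instruments) yield a flagged row and
#' the run continues.  With an output directory set, writes
#' `results.tsv`, per-pair `scatter/<exposure>_<outcome>.tsv`,
#' `exclusions.tsv` and `run.log`; outputs are byte-identical across
#' reruns with the same config and seed.
#'
#' @param cfg a [StudyConfig-class].
#' @return The results data.frame (one row per exposure, outcome and
#'   method, with q-values in `fdr_q`).
#' @export
runUnivariable <- function(cfg) {
  stopifnot(is(cfg, "StudyConfig"))
  validObject(cfg)
  exps <- lapply(cfg@exposures, loadTrait, default_type = "quantitative")
  outs <- lapply(cfg@outcomes, loadTrait, default_type = "binary")
  ld <- loadLd(cfg@ldSource)
  pol <- cfg@policies$palindromic_policy %||% "exclude"
  band <- cfg@policies$eaf_band %||% c(0.42, 0.58)
  n_pairs <- length(exps) * length(outs)
  seeds <- deriveSeeds(cfg@seed, n_pairs)
  rows <- list()
  scatters <- list()
  excl <- list()
  logline <- c(sprintf("master seed: %d", cfg@seed),
               sprintf("thresholds: p<%g, clump r2 %g, window %g kb, maf %g, proxy r2 %g",
                       cfg@thresholds$p_threshold, cfg@thresholds$clump_r2,
                       cfg@thresholds$clump_window_kb, cfg@thresholds$maf_min,
                       cfg@thresholds$proxy_r2),
               sprintf("palindromic policy: %s", pol),
               "fdr family: exposures within (outcome, method)")
  pair_i <- 0
  for (oi in seq_along(outs)) {
    for (ei in seq_along(exps)) {
      pair_i <- pair_i + 1
      ename <- exps[[ei]]@traitName
      oname <- outs[[oi]]@traitName
      pair_seed <- seeds[pair_i]
      result <- tryCatch({
        iset <- buildInstrumentSet(exps[[ei]], outs[[oi]], ld,
                                   cfg@thresholds)
        h <- harmonizeAll(iset, outs[[oi]], policy = pol, eaf_band = band)
        n <- nVariants(h)
        excl[[pair_i]] <- if (nrow(exclusions(h)))
          cbind(exposure = ename, outcome = oname, exclusions(h)) else NULL
        scatters[[paste(ename, oname, sep = "_")]] <- harmonizedData(h)
        prows <- list()
        iv <- mrIvw(h)
        qex <- list(q = if (!is.null(iv$heterogeneity)) iv$heterogeneity@q else NA_real_,
                    qp = if (!is.null(iv$heterogeneity)) iv$heterogeneity@pvalue else NA_real_,
                    mean_f = meanF(iset))
        if (n == 1) {
          d <- harmonizedData(h)
          prows$wald <- estimateRow(ename, oname,
                                    waldRatio(d$beta_exposure, d$beta_outcome,
                                              d$se_outcome),
                                    list(mean_f = meanF(iset)))
        }
        if ("ivw" %in% cfg@methods)
          prows$ivw <- estimateRow(ename, oname, iv$estimate, qex)
        if ("egger" %in% cfg@methods && n >= 3) {
          eg <- mrEgger(h)
          prows$egger <- estimateRow(ename, oname, eg$estimate,
                                     list(q = eg$heterogeneity@q,
                                          qp = eg$heterogeneity@pvalue,
                                          eip = eg$pleiotropy@pvalue,
                                          mean_f = meanF(iset)))
        }
        if ("weighted_median" %in% cfg@methods && n >= 3)
          prows$wm <- estimateRow(ename, oname,
                                  weightedMedian(h, seed = pair_seed),
                                  list(mean_f = meanF(iset)))
        if ("weighted_mode" %in% cfg@methods && n >= 3)
          prows$wmo <- estimateRow(ename, oname,
                                   weightedMode(h, seed = pair_seed),
                                   list(mean_f = meanF(iset)))
        if ("mrpresso" %in% cfg@methods && n >= 4) {
          pr <- mrPresso(h, seed = pair_seed)
          beta_pr <- if (!is.na(pr@betaCorrected)) pr@betaCorrected else pr@betaRaw
          n_pr <- n - length(pr@outlierIndices)
          se_pr <- {
            keep <- setdiff(seq_len(n), pr@outlierIndices)
            d <- harmonizedData(h)
            sqrt(1 / sum(d$beta_exposure[keep]^2 / d$se_outcome[keep]^2))
          }
          prows$presso <- estimateRow(
            ename, oname,
            newMREstimate("mrpresso", beta_pr, se_pr, n_pr),
            list(qp = pr@globalPvalue,
                 flags = if (length(pr@outlierIndices))
                   paste0("outliers_removed:", length(pr@outlierIndices))
                 else ""))
        }
        do.call(rbind, prows)
      }, error = function(e) {
        estimateRow(ename, oname,
                    newMREstimate("failed", 0, 1, 0L, pvalue = 1),
                    list(flags = paste0("failed:", conditionMessage(e))))
      })
      rows[[pair_i]] <- result
      logline <- c(logline, sprintf("pair %s ~ %s: seed %d, %d row(s)",
                                    ename, oname, pair_seed, nrow(result)))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr_q <- NA_real_
  ok <- res$method != "failed"
  for (fam in split(which(ok), list(res$outcome[ok], res$method[ok]),
                    drop = TRUE))
    res$fdr_q[fam] <- benjaminiHochberg(res$pvalue[fam])
  if (nzchar(cfg@outputDir)) {
    dir.create(cfg@outputDir, showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(cfg@outputDir, "scatter"), showWarnings = FALSE)
    utils::write.table(numFmt(res), file.path(cfg@outputDir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(scatters))
      utils::write.table(numFmt(scatters[[nm]]),
                         file.path(cfg@outputDir, "scatter",
                                   paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ex <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
    if (is.null(ex))
      ex <- data.frame(exposure = character(), outcome = character(),
                       snp_id = character(), reason = character())
    utils::write.table(ex, file.path(cfg@outputDir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(logline, file.path(cfg@outputDir, "run.log"))
  }
  res
}

#' Run the multivariable MR analysis of a study
#'
#' Builds per-exposure instrument sets against each outcome, assembles
#' the combined multivariable design ([assembleMvmrInput()]), fits
#' [mvmrIvw()] (extended with covariates via [mvmrWithCovariates()] when
#' given), and applies FDR across exposures within each outcome.
#'
#' @param cfg a [StudyConfig-class] with at least two exposures.
#' @param covariates optional list of covariate trait entries (same form
#'   as `cfg@exposures`).
#' @return data.frame with one row per exposure (and covariate) per
#'   outcome, including the combined instrument count `n_snp` and
#'   `fdr_q`.
#' @export
runMvmr <- function(cfg, covariates = NULL) {
  stopifnot(is(cfg, "StudyConfig"))
  validObject(cfg)
  if (length(cfg@exposures) < 2) stop("runMvmr needs at least 2 exposures")
  exps <- lapply(cfg@exposures, loadTrait, default_type = "quantitative")
  outs <- lapply(cfg@outcomes, loadTrait, default_type = "binary")
  covs <- if (!is.null(covariates))
    lapply(covariates, loadTrait, default_type = "quantitative") else NULL
  ld <- loadLd(cfg@ldSource)
  pol <- cfg@policies$palindromic_policy %||% "exclude"
  band <- cfg@policies$eaf_band %||% c(0.42, 0.58)
  rows <- list()
  for (oi in seq_along(outs)) {
    oname <- outs[[oi]]@traitName
    isets <- lapply(exps, buildInstrumentSet, outcome = outs[[oi]],
                    ld = ld, params = cfg@thresholds)
    m <- assembleMvmrInput(isets, exps, outs[[oi]], ld, cfg@thresholds,
                           policy = pol, eaf_band = band)
    fit <- if (length(covs)) mvmrWithCovariates(m, covs, policy = pol,
                                                eaf_band = band)
           else mvmrIvw(m)
    tab <- estimateTable(fit)
    tab$outcome <- oname
    tab$n_snp <- fit@nSnp
    tab$fdr_q <- benjaminiHochberg(tab$pvalue)
    rows[[oi]] <- tab
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res <- res[, c("exposure", "outcome", "n_snp", "beta", "se", "ci_low",
                 "ci_high", "pvalue", "fdr_q", "or", "or_ci_low",
                 "or_ci_high", "conditional_f")]
  if (nzchar(cfg@outputDir)) {
    dir.create(cfg@outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(numFmt(res),
                       file.path(cfg@outputDir, "mvmr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
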