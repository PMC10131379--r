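simMvmrInput <- function(seed = 1, n = 40, k = 2,
                         direct = c(0.15, 0.15), corr = diag(k)) {
  mv <- simulateMvmr(simConfig(n_snps = n, seed = seed), k, direct, corr)
  MVMRInput(
    exposure_betas = sapply(mv$exposures, function(g) variants(g)$beta),
    exposure_ses = sapply(mv$exposures, function(g) variants(g)$se),
    outcome_beta = variants(mv$outcome)$beta,
    outcome_se = variants(mv$outcome)$se,
    snp_ids = variants(mv$outcome)$snp_id,
    exposure_names = names(mv$exposures))
}

test_that("K = 1 multivariable IVW equals the univariable fixed-effect IVW", {
  m <- simMvmrInput(seed = 2, k = 1, direct = 0.2, corr = diag(1))
  uni <- mrIvw(HarmonizedSet(m@snpIds, m@exposureBetas[, 1],
                             m@exposureSes[, 1], m@outcomeBeta,
                             m@outcomeSe), model = "fixed")
  fit <- mvmrIvw(m)
  expect_equal(estimateTable(fit)$beta, uni$estimate@beta,
               tolerance = 1e-10)
})

test_that("estimates are invariant to exposure-column and SNP order", {
  m <- simMvmrInput(seed = 3)
  fit <- mvmrIvw(m)
  m_sw <- MVMRInput(m@exposureBetas[, 2:1], m@exposureSes[, 2:1],
                    m@outcomeBeta, m@outcomeSe, m@snpIds,
                    m@exposureNames[2:1])
  fit_sw <- mvmrIvw(m_sw)
  expect_equal(estimateTable(fit)$beta,
               rev(estimateTable(fit_sw)$beta), tolerance = 1e-12)
  perm <- withr::with_seed(1, sample(length(m@snpIds)))
  m_p <- MVMRInput(m@exposureBetas[perm, ], m@exposureSes[perm, ],
                   m@outcomeBeta[perm], m@outcomeSe[perm],
                   m@snpIds[perm], m@exposureNames)
  expect_equal(estimateTable(mvmrIvw(m_p))$beta,
               estimateTable(fit)$beta, tolerance = 1e-12)
})

test_that("a duplicated exposure column raises a collinearity error", {
  m <- simMvmrInput(seed = 4)
  dup <- MVMRInput(m@exposureBetas[, c(1, 1)], m@exposureSes[, c(1, 1)],
                   m@outcomeBeta, m@outcomeSe, m@snpIds,
                   c("expA", "expA_copy"))
  expect_error(mvmrIvw(dup), "collinear")
})

test_that("assembly takes the union of instruments and drops LD duplicates", {
  # 25 shared variants; exposure A instruments 1..10 u 21..25,
  # exposure B instruments 11..25: union is all 25
  mv <- simulateMvmr(simConfig(n_snps = 25, gamma_sd = 0.08, seed = 6,
                               palindromic_fraction = 0), 2,
                     direct_effects = c(0.2, 0.1))
  ids <- variants(mv$outcome)$snp_id
  ld <- LDMatrix(diag(25), snpIds = ids)
  mkIset <- function(g, take) {
    v <- variants(g)[take, ]
    new("InstrumentSet", variants = v,
        perSnpR2 = varianceExplained(v$beta, v$eaf),
        totalR2 = sum(varianceExplained(v$beta, v$eaf)),
        meanF = 100, jointF = 100,
        provenance = data.frame(snp_id = v$snp_id, genome_wide = TRUE,
                                clump_kept = TRUE, maf_pass = TRUE,
                                proxy_used = FALSE,
                                outcome_snp_id = v$snp_id),
        exposureN = 1e5)
  }
  isets <- list(mkIset(mv$exposures[[1]], c(1:10, 21:25)),
                mkIset(mv$exposures[[2]], 11:25))
  m <- assembleMvmrInput(isets, mv$exposures, mv$outcome, ld)
  expect_equal(length(m@snpIds), 25)
  # plant LD between two cross-exposure instruments: one must go
  r2 <- diag(25); dimnames(r2) <- list(ids, ids)
  r2[1, 11] <- r2[11, 1] <- 0.9
  # put them within one clump window on the same chromosome, in both files
  v1 <- variants(mv$exposures[[1]])
  v2 <- variants(mv$exposures[[2]])
  v1$chrom[c(1, 11)] <- v2$chrom[c(1, 11)] <- "1"
  v1$pos[c(1, 11)] <- v2$pos[c(1, 11)] <- c(1e6L, 2e6L)
  expA <- GwasSummary(v1, traitName = "exposure1")
  expB <- GwasSummary(v2, traitName = "exposure2")
  isets2 <- list(mkIset(expA, c(1:10, 21:25)), mkIset(expB, 11:25))
  m2 <- assembleMvmrInput(isets2, list(expA, expB),
                          mv$outcome, LDMatrix(r2))
  expect_equal(length(m2@snpIds), 24)
  expect_false(all(c(ids[1], ids[11]) %in% m2@snpIds))
})

test_that("assembly fails when fewer SNPs than exposures survive", {
  mv <- simulateMvmr(simConfig(n_snps = 3, seed = 7,
                               palindromic_fraction = 0), 2,
                     direct_effects = c(0.2, 0.1))
  ids <- variants(mv$outcome)$snp_id
  ld <- LDMatrix(matrix(1, 3, 3, dimnames = list(ids, ids)))
  v <- variants(mv$exposures[[1]])
  v$chrom <- "1"; v$pos <- c(1e6L, 2e6L, 3e6L)
  iset <- new("InstrumentSet", variants = v,
              perSnpR2 = rep(0.001, 3), totalR2 = 0.003,
              meanF = 100, jointF = 100,
              provenance = data.frame(snp_id = v$snp_id, genome_wide = TRUE,
                                      clump_kept = TRUE, maf_pass = TRUE,
                                      proxy_used = FALSE,
                                      outcome_snp_id = v$snp_id),
              exposureN = 1e5)
  expect_error(
    assembleMvmrInput(list(iset, iset),
                      list(GwasSummary(v, traitName = "e1"),
                           GwasSummary(v, traitName = "e2")),
                      mv$outcome, ld),
    "J = 1")
})

test_that("null, uncorrelated covariates leave estimates nearly unchanged", {
  mv <- simulateMvmr(simConfig(n_snps = 60, seed = 8,
                               palindromic_fraction = 0), 2,
                     direct_effects = c(0.2, 0))
  m <- simMvmrInput(seed = 8, n = 60, k = 2, direct = c(0.2, 0))
  # covariate trait: same SNPs, independent null effects
  covsim <- simulateTwoSample(simConfig(n_snps = 60, causal_effect = 0,
                                        seed = 99,
                                        palindromic_fraction = 0))
  covv <- variants(covsim$exposure)
  # align ids and alleles with the MVMR frame so harmonization passes through
  covv$snp_id <- m@snpIds
  covv$effect_allele <- "A"; covv$other_allele <- "G"
  fit0 <- mvmrIvw(m)
  fitc <- mvmrWithCovariates(m, list(GwasSummary(covv, traitName = "cov")))
  t0 <- estimateTable(fit0)
  tc <- estimateTable(fitc)
  expect_equal(nrow(tc), 3)
  expect_lt(abs(t0$beta[1] - tc$beta[1]), 3 * sqrt(t0$se[1]^2 + tc$se[1]^2))
})

test_that("conditional instrument strength is reported for every exposure", {
  m <- simMvmrInput(seed = 11)
  tab <- estimateTable(mvmrIvw(m))
  expect_true(all(is.finite(tab$conditional_f)))
  expect_true(all(tab$conditional_f > 0))
})
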