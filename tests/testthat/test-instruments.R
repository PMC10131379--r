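test_that("genome-wide selection uses a strict threshold", {
  v <- makeVariants(3, pvalue = c(4.9e-8, 5e-8, 1e-9))
  g <- GwasSummary(v)
  kept <- selectGenomeWide(g)
  expect_setequal(kept$snp_id, v$snp_id[c(1, 3)])
  v$pvalue <- rep(0.5, 3)
  expect_message(kept2 <- selectGenomeWide(GwasSummary(v)), "no variant")
  expect_equal(nrow(kept2), 0)
  sim <- simulateTwoSample(simConfig(n_snps = 200, gamma_sd = 0.03, seed = 3))
  kept3 <- selectGenomeWide(sim$exposure)
  expect_equal(nrow(kept3),
               sum(variants(sim$exposure)$pvalue < 5e-8))
})

test_that("clumping keeps the lower-p SNP of a correlated pair", {
  cand <- makeVariants(2, pvalue = c(1e-9, 1e-10),
                       pos = c(1000L, 2000L), chrom = c("1", "1"))
  m <- matrix(c(1, 0.5, 0.5, 1), 2,
              dimnames = list(cand$snp_id, cand$snp_id))
  kept <- clumpVariants(cand, LDMatrix(m))
  expect_equal(kept$snp_id, cand$snp_id[2])  # the p = 1e-10 SNP
  # same pair far outside the window survives intact
  cand$pos <- c(1000L, 2000000000L)  # ~2e9 bp apart >> 5e6 half-window
  kept2 <- clumpVariants(cand, LDMatrix(m))
  expect_equal(nrow(kept2), 2)
})

test_that("clumping matches an independent greedy reference on random instances", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- 50
      cand <- makeVariants(n, seed = seed,
                           chrom = as.character(sample(1:3, n, TRUE)),
                           pos = as.integer(sample(1e6:2e7, n)),
                           pvalue = runif(n, 1e-12, 1e-4))
      a <- matrix(runif(n * n), n)
      r2 <- (a + t(a)) / 2
      diag(r2) <- 1
      dimnames(r2) <- list(cand$snp_id, cand$snp_id)
    })
    kept <- clumpVariants(cand, LDMatrix(r2), r2_threshold = 0.6,
                          window_kb = 10000)
    expect_identical(kept$snp_id, bruteClump(cand, r2, 0.6, 10000))
  }
})

test_that("clumped output is pairwise r2-compatible within the window", {
  out <- simulateLdBlockGwas(simConfig(n_snps = 50, ld_block_size = 5,
                                       ld_within_block_r2 = 0.8, seed = 2))
  kept <- clumpVariants(variants(out$gwas), out$ld, 0.01, 10000)
  expect_equal(nrow(kept), 10)  # one survivor per block
  m <- r2Matrix(out$ld)
  for (i in seq_len(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
    same <- kept$chrom[i] == kept$chrom[j] &&
      abs(kept$pos[i] - kept$pos[j]) <= 5e6
    if (same) expect_lt(m[kept$snp_id[i], kept$snp_id[j]], 0.01)
  }
  # with no LD, clumping keeps everything
  out0 <- simulateLdBlockGwas(simConfig(n_snps = 50, ld_block_size = 5,
                                        ld_within_block_r2 = 0, seed = 2))
  expect_equal(nrow(clumpVariants(variants(out0$gwas), out0$ld, 0.01, 10000)),
               50)
})

test_that("MAF filter keeps the 1% boundary and matches brute force", {
  v <- makeVariants(4, eaf = c(0.995, 0.01, 0.5, 0.004))
  kept <- filterMaf(v)
  expect_setequal(kept$snp_id, v$snp_id[c(2, 3)])
  v2 <- makeVariants(100, seed = 8, eaf = runif(100, 0, 1))
  expect_identical(filterMaf(v2)$snp_id,
                   v2$snp_id[pmin(v2$eaf, 1 - v2$eaf) >= 0.01])
})

test_that("proxy lookup returns the strongest proxy above the strict bound", {
  ov <- makeVariants(3, pvalue = c(1e-6, 1e-6, 1e-6))
  outcome <- GwasSummary(ov, traitType = "binary", nTotal = 100, nCases = 40)
  ids <- c("target", ov$snp_id)
  r2 <- diag(4)
  dimnames(r2) <- list(ids, ids)
  r2["target", ov$snp_id] <- r2[ov$snp_id, "target"] <- c(0.85, 0.95, 0.2)
  ld <- LDMatrix(r2)
  px <- findProxy("target", outcome, ld)
  expect_equal(px$snp_id, ov$snp_id[2])
  # exactly 0.8 is not a proxy (strict inequality)
  r2["target", ov$snp_id] <- r2[ov$snp_id, "target"] <- c(0.8, 0.8, 0.2)
  expect_null(findProxy("target", outcome, LDMatrix(r2)))
  expect_warning(res <- findProxy("unknown", outcome, ld), "unknown")
  expect_null(res)
})

test_that("variance explained and F statistic match direct arithmetic", {
  expect_equal(varianceExplained(0, 0.3), 0)
  expect_equal(varianceExplained(0.1, 0.5), 0.005, tolerance = 1e-12)
  expect_equal(varianceExplained(0.1, 0), 0)
  expect_equal(varianceExplained(0.1, 1), 0)
  expect_equal(fStatistic(0, 1000, 1), 0)
  expect_equal(fStatistic(0.005, 1e5, 1), 0.005 * (1e5 - 2) / 0.995,
               tolerance = 1e-12)
  r2s <- seq(0.001, 0.05, by = 0.001)
  expect_true(all(diff(fStatistic(r2s, 1e5, 3)) > 0))  # monotone in R2
  expect_error(fStatistic(1, 100, 1), "r2_total")
  expect_error(fStatistic(0.1, 3, 2), "n must exceed")
})

test_that("the full QC cascade yields strong instruments on strong data", {
  sim <- simulateTwoSample(simConfig(n_snps = 150, gamma_sd = 0.05,
                                     seed = 14))
  ld <- LDMatrix(diag(150), snpIds = variants(sim$exposure)$snp_id)
  iset <- buildInstrumentSet(sim$exposure, sim$outcome, ld)
  expect_gt(meanF(iset), 10)
  expect_true(all(snpIds(iset) %in% snpIds(sim$exposure)))
  expect_true(all(variants(iset)$pvalue < 5e-8))
  expect_equal(totalR2(iset), sum(iset@perSnpR2))
})

test_that("weak instruments trigger a warning and tiny effects select nothing", {
  sim <- simulateTwoSample(simConfig(n_snps = 100, gamma_sd = 0.008,
                                     n_exposure = 2e4, seed = 23))
  ld <- LDMatrix(diag(100), snpIds = variants(sim$exposure)$snp_id)
  # significance filtering under weak effects: few/no SNPs pass
  kept <- selectGenomeWide(sim$exposure)
  if (nrow(kept) == 0) {
    expect_error(buildInstrumentSet(sim$exposure, sim$outcome, ld),
                 "no instruments")
  } else {
    # relax the p threshold to force weakly informative instruments through
    params <- instrumentParams(p_threshold = 0.5)
    expect_warning(iset <- buildInstrumentSet(sim$exposure, sim$outcome,
                                              ld, params),
                   "weak instruments")
    expect_lte(meanF(iset), 10)
  }
})

test_that("filter order commutes when no SNP is hit by both filters", {
  v <- makeVariants(20, seed = 6, eaf = c(runif(18, 0.2, 0.8), 0.003, 0.002))
  ld <- LDMatrix(diag(20), snpIds = v$snp_id)
  a <- filterMaf(clumpVariants(v, ld))
  b <- clumpVariants(filterMaf(v), ld)
  expect_setequal(a$snp_id, b$snp_id)
})
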