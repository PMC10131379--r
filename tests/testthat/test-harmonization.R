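mkVar <- function(id, ea, oa, eaf, beta, se = 0.01, p = 1e-9) {
  data.frame(snp_id = id, chrom = "1", pos = 100L, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = p, n = 1e5, stringsAsFactors = FALSE)
}

test_that("palindromic detection covers all allele pairs", {
  expect_true(isPalindromic("A", "T"))
  expect_true(isPalindromic("T", "A"))
  expect_true(isPalindromic("C", "G"))
  expect_true(isPalindromic("G", "C"))
  expect_false(isPalindromic("A", "G"))
  expect_false(isPalindromic("C", "T"))
  expect_error(isPalindromic("A", "N"))
})

test_that("swapped alleles flip the outcome beta and frequency", {
  h <- harmonizePair(mkVar("rs1", "A", "G", 0.3, 0.1),
                     mkVar("rs1", "G", "A", 0.7, -0.05))
  expect_equal(h$status, "ok")
  expect_true("allele_flipped" %in% h$flags)
  expect_equal(h$outcome$beta, 0.05)
  expect_equal(h$outcome$eaf, 0.3)
  expect_equal(h$outcome$effect_allele, "A")
})

test_that("strand-complement matches are repaired before comparison", {
  # exposure A/G; outcome reported on the other strand as T/C
  h <- harmonizePair(mkVar("rs1", "A", "G", 0.3, 0.1),
                     mkVar("rs1", "T", "C", 0.3, 0.04))
  expect_equal(h$status, "ok")
  expect_equal(h$outcome$beta, 0.04)
  # complement-swapped: C/T vs A/G
  h2 <- harmonizePair(mkVar("rs1", "A", "G", 0.3, 0.1),
                      mkVar("rs1", "C", "T", 0.7, 0.04))
  expect_true("allele_flipped" %in% h2$flags)
  expect_equal(h2$outcome$beta, -0.04)
  # unconcordant allele sets are dropped
  h3 <- harmonizePair(mkVar("rs1", "A", "G", 0.3, 0.1),
                      mkVar("rs1", "A", "C", 0.3, 0.04))
  expect_equal(h3$status, "excluded")
  expect_equal(h3$reason, "excluded_ambiguous")
})

test_that("palindromic policy: exclude drops, infer orients by frequency", {
  ex <- mkVar("rs1", "A", "T", 0.2, 0.1)
  out_aligned <- mkVar("rs1", "A", "T", 0.22, 0.05)
  out_flipped <- mkVar("rs1", "A", "T", 0.78, 0.05)
  expect_equal(harmonizePair(ex, out_aligned)$status, "excluded")
  h <- harmonizePair(ex, out_aligned, policy = "infer_by_eaf")
  expect_equal(h$status, "ok")
  expect_equal(h$outcome$beta, 0.05)
  h2 <- harmonizePair(ex, out_flipped, policy = "infer_by_eaf")
  expect_equal(h2$status, "ok")
  expect_equal(h2$outcome$beta, -0.05)
  expect_true("allele_flipped" %in% h2$flags)
  # a frequency inside the ambiguity band blocks inference
  h3 <- harmonizePair(mkVar("rs1", "A", "T", 0.5, 0.1), out_aligned,
                      policy = "infer_by_eaf")
  expect_equal(h3$status, "excluded")
})

test_that("harmonization is idempotent on its own output", {
  h <- harmonizePair(mkVar("rs1", "A", "G", 0.3, 0.1),
                     mkVar("rs1", "G", "A", 0.7, -0.05))
  h2 <- harmonizePair(h$exposure, h$outcome)
  expect_equal(h2$status, "ok")
  expect_equal(h2$outcome, h$outcome)
})

test_that("a constructed fixture loses palindromic SNPs and flips signs", {
  n <- 10
  ev <- makeVariants(n, seed = 3)  # A/G and C/T pairs, non-palindromic
  ev$effect_allele[9:10] <- c("A", "C")
  ev$other_allele[9:10] <- c("T", "G")
  ov <- ev
  ov$beta <- rnorm(n, 0, 0.02)
  # swap alleles (and orientation) for the first three SNPs
  tmp <- ov$effect_allele[1:3]
  ov$effect_allele[1:3] <- ov$other_allele[1:3]
  ov$other_allele[1:3] <- tmp
  ov$eaf[1:3] <- 1 - ov$eaf[1:3]
  exposure <- GwasSummary(ev)
  outcome <- GwasSummary(ov, traitType = "binary", nTotal = 4e4,
                         nCases = 2e4)
  h <- harmonizeSummaries(exposure, outcome, policy = "exclude")
  expect_equal(nVariants(h), n - 2)
  expect_equal(sort(exclusions(h)$snp_id), sort(ev$snp_id[9:10]))
  d <- harmonizedData(h)
  flipped <- d$snp_id %in% ev$snp_id[1:3]
  expect_equal(d$beta_outcome[flipped],
               -ov$beta[match(d$snp_id[flipped], ov$snp_id)])
  expect_equal(d$beta_outcome[!flipped],
               ov$beta[match(d$snp_id[!flipped], ov$snp_id)])
})

test_that("tightening the ambiguity band never excludes fewer SNPs", {
  sim <- simulateTwoSample(simConfig(n_snps = 200,
                                     palindromic_fraction = 0.5, seed = 19))
  bands <- list(c(0.45, 0.55), c(0.42, 0.58), c(0.3, 0.7))
  n_excl <- vapply(bands, function(b)
    nrow(exclusions(harmonizeSummaries(sim$exposure, sim$outcome,
                                       policy = "infer_by_eaf",
                                       eaf_band = b))), numeric(1))
  expect_true(all(diff(n_excl) >= 0))
})

test_that("downstream estimates are invariant to allele recoding of an input", {
  sim <- simulateTwoSample(simConfig(n_snps = 60, seed = 44))
  exposure <- sim$exposure
  recoded <- variants(exposure)
  tmp <- recoded$effect_allele
  recoded$effect_allele <- recoded$other_allele
  recoded$other_allele <- tmp
  recoded$beta <- -recoded$beta
  recoded$eaf <- 1 - recoded$eaf
  exposure2 <- GwasSummary(recoded, traitName = exposure@traitName)
  h1 <- harmonizeSummaries(exposure, sim$outcome)
  h2 <- harmonizeSummaries(exposure2, sim$outcome)
  for (fit in list(mrIvw, function(h) list(estimate = mrEgger(h)$estimate))) {
    e1 <- fit(h1)$estimate
    e2 <- fit(h2)$estimate
    expect_equal(e1@beta, e2@beta, tolerance = 1e-12)
    expect_equal(e1@se, e2@se, tolerance = 1e-12)
  }
})

test_that("harmonizeAll errors when everything is excluded", {
  ev <- makeVariants(3)
  ev$effect_allele <- "A"; ev$other_allele <- "T"  # all palindromic
  ov <- ev
  iset <- new("InstrumentSet", variants = ev,
              perSnpR2 = varianceExplained(ev$beta, ev$eaf),
              totalR2 = sum(varianceExplained(ev$beta, ev$eaf)),
              meanF = 100, jointF = 100,
              provenance = data.frame(snp_id = ev$snp_id,
                                      genome_wide = TRUE, clump_kept = TRUE,
                                      maf_pass = TRUE, proxy_used = FALSE,
                                      outcome_snp_id = ev$snp_id),
              exposureN = 1e5)
  expect_error(harmonizeAll(iset, GwasSummary(ov), policy = "exclude"),
               "all SNPs excluded")
})
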