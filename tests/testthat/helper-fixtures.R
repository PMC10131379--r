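# Fixture builders and independent oracles used across the suite.

makeVariants <- function(n, seed = 1, chrom = NULL, pos = NULL,
                         pvalue = NULL, eaf = NULL, beta = NULL) {
  withr::with_seed(seed, {
    data.frame(
      snp_id = sprintf("rs%04d", seq_len(n)),
      chrom = chrom %||% as.character(rep(1, n)),
      pos = pos %||% as.integer(seq_len(n) * 2e7),
      effect_allele = rep(c("A", "C"), length.out = n),
      other_allele = rep(c("G", "T"), length.out = n),
      eaf = eaf %||% runif(n, 0.1, 0.9),
      beta = beta %||% rnorm(n, 0, 0.05),
      se = runif(n, 0.004, 0.006),
      pvalue = pvalue %||% runif(n, 1e-12, 1e-9),
      n = rep(1e5, n),
      stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

makeHarmonized <- function(bx, by, sy, sx = rep(1e-3, length(bx))) {
  HarmonizedSet(snp_id = sprintf("rs%04d", seq_along(bx)),
                beta_exposure = bx, se_exposure = sx,
                beta_outcome = by, se_outcome = sy)
}

# Independent greedy-clumping reference: explicit double loop, no shared
# code with clumpVariants.
bruteClump <- function(cand, r2mat, r2_threshold, window_kb) {
  half <- window_kb * 1000 / 2
  cand <- cand[order(cand$pvalue, cand$snp_id), ]
  alive <- rep(TRUE, nrow(cand))
  kept <- character()
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    kept <- c(kept, cand$snp_id[i])
    if (i == nrow(cand)) break
    for (j in (i + 1):nrow(cand)) {
      if (!alive[j]) next
      same_chr <- cand$chrom[j] == cand$chrom[i]
      close <- abs(cand$pos[j] - cand$pos[i]) <= half
      a <- cand$snp_id[i]; b <- cand$snp_id[j]
      r2 <- if (a %in% rownames(r2mat) && b %in% rownames(r2mat))
        r2mat[a, b] else 0
      if (same_chr && close && r2 >= r2_threshold) alive[j] <- FALSE
    }
  }
  kept
}

# Independent weighted-median reference: replicate each ratio in
# proportion to its weight and take the plain sample median.
bruteWeightedMedian <- function(theta, w, reps = 20000) {
  counts <- round(w / sum(w) * reps)
  stats::median(rep(theta, times = counts))
}

# Independent step-up BH reference.
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

# Fixed-effect IVW via the weighted normal equations on (bx, by).
bruteIvwSlope <- function(bx, by, sy) {
  w <- 1 / sy^2
  solve(t(bx * w) %*% bx, t(bx * w) %*% by)[1, 1]
}
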