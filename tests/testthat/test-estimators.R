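test_that("Wald ratio matches direct arithmetic and its invariances", {
  w <- waldRatio(0.1, 0.05, 0.01)
  expect_equal(w@beta, 0.5, tolerance = 1e-12)
  expect_equal(w@se, 0.1, tolerance = 1e-12)
  z <- waldRatio(0.1, 0, 0.01)
  expect_equal(z@beta, 0)
  expect_equal(z@pvalue, 1)
  a <- waldRatio(0.1, 0.05, 0.01)
  b <- waldRatio(-0.3, -0.15, 0.01)  # scaling bx, by by c = -3
  expect_equal(a@beta, b@beta, tolerance = 1e-12)
  expect_error(waldRatio(0, 0.05, 0.01), "zero")
})

test_that("IVW reproduces the worked two-SNP example and the Wald degenerate case", {
  h2 <- makeHarmonized(bx = c(0.1, 0.2), by = c(0.05, 0.04),
                       sy = c(0.01, 0.02))
  fit <- mrIvw(h2, model = "fixed")
  expect_equal(fit$estimate@beta, 0.35, tolerance = 1e-12)
  expect_equal(fit$estimate@se, sqrt(1 / 200), tolerance = 1e-12)
  h1 <- makeHarmonized(0.1, 0.05, 0.01)
  expect_equal(mrIvw(h1)$estimate@beta, waldRatio(0.1, 0.05, 0.01)@beta)
  expect_equal(mrIvw(h1)$estimate@se, waldRatio(0.1, 0.05, 0.01)@se)
})

test_that("IVW equals the weighted-LS-through-origin oracle; Q behaves", {
  withr::with_seed(10, {
    bx <- rnorm(30, 0, 0.05)
    by <- 0.2 * bx + rnorm(30, 0, 0.01)
    sy <- runif(30, 0.005, 0.02)
  })
  h <- makeHarmonized(bx, by, sy)
  fit <- mrIvw(h, model = "fixed")
  expect_equal(fit$estimate@beta, bruteIvwSlope(bx, by, sy),
               tolerance = 1e-10)
  expect_equal(fit$estimate@beta,
               unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2))),
               tolerance = 1e-10)
  # identical ratios: no heterogeneity at all
  hc <- makeHarmonized(c(0.1, 0.2, 0.4), c(0.05, 0.1, 0.2),
                       c(0.01, 0.01, 0.01))
  fitc <- mrIvw(hc)
  expect_equal(fitc$heterogeneity@q, 0, tolerance = 1e-20)
  expect_equal(fitc$heterogeneity@pvalue, 1)
  # multiplicative random effects never deflates the SE
  expect_gte(mrIvw(h)$estimate@se, mrIvw(h, "fixed")$estimate@se)
})

test_that("Egger recovers an exact linear law and its weighted-LS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- 0.01 + 0.3 * bx
  h <- makeHarmonized(bx, by, sy = rep(0.01, 4))
  fit <- mrEgger(h)
  expect_equal(fit$estimate@beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$pleiotropy@intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit$heterogeneity@q, 0, tolerance = 1e-16)
  withr::with_seed(3, {
    bx <- abs(rnorm(25, 0, 0.05))
    by <- 0.02 + 0.25 * bx + rnorm(25, 0, 0.01)
    sy <- runif(25, 0.008, 0.02)
  })
  h2 <- makeHarmonized(bx, by, sy)
  ref <- lm(by ~ bx, weights = 1 / sy^2)
  fit2 <- mrEgger(h2)
  expect_equal(fit2$estimate@beta, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit2$pleiotropy@intercept, unname(coef(ref)[1]),
               tolerance = 1e-10)
  expect_error(mrEgger(makeHarmonized(c(0.1, 0.2), c(0.01, 0.02),
                                      c(0.01, 0.01))), "3 SNPs")
})

test_that("Egger orientation makes it invariant to per-SNP sign flips", {
  withr::with_seed(5, {
    bx <- rnorm(20, 0, 0.05)
    by <- 0.2 * bx + rnorm(20, 0, 0.01)
    sy <- runif(20, 0.008, 0.02)
  })
  flip <- rep(c(1, -1), 10)
  f1 <- mrEgger(makeHarmonized(bx, by, sy))
  f2 <- mrEgger(makeHarmonized(bx * flip, by * flip, sy))
  expect_equal(f1$estimate@beta, f2$estimate@beta, tolerance = 1e-12)
  expect_equal(f1$pleiotropy@intercept, f2$pleiotropy@intercept,
               tolerance = 1e-12)
})

test_that("weighted median: plain median, dominant atom, replication oracle", {
  h <- makeHarmonized(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                      sy = c(1, 1, 1))
  expect_equal(weightedMedian(h, n_boot = 50)@beta, 0.2)
  # even count with equal weights averages the middle pair
  h4 <- makeHarmonized(bx = rep(1, 4), by = c(0.1, 0.2, 0.3, 0.4),
                       sy = rep(1, 4))
  expect_equal(weightedMedian(h4, n_boot = 50)@beta, 0.25)
  # > 50% of the weight on one SNP returns its ratio exactly
  hdom <- makeHarmonized(bx = c(1, 1, 1), by = c(0.8, 0.2, 0.9),
                         sy = c(sqrt(1 / 0.6), sqrt(1 / 0.25),
                                sqrt(1 / 0.15)))
  expect_equal(weightedMedian(hdom, n_boot = 50)@beta, 0.8)
  withr::with_seed(9, {
    bx <- abs(rnorm(15, 0, 0.05)) + 0.01
    by <- 0.2 * bx + rnorm(15, 0, 0.005)
    sy <- runif(15, 0.005, 0.02)
  })
  h15 <- makeHarmonized(bx, by, sy)
  theta <- by / bx
  w <- (bx^2 / sy^2) / sum(bx^2 / sy^2)
  expect_equal(weightedMedian(h15, n_boot = 50)@beta,
               bruteWeightedMedian(theta, w), tolerance = 1e-6)
  # bootstrap SE is deterministic under the seed
  expect_identical(weightedMedian(h15, seed = 7)@se,
                   weightedMedian(h15, seed = 7)@se)
})

test_that("weighted mode finds the dominant cluster and is order-invariant", {
  hconst <- makeHarmonized(bx = c(1, 1, 1), by = c(0.25, 0.25, 0.25),
                           sy = c(0.1, 0.1, 0.1))
  expect_equal(weightedMode(hconst, n_boot = 50)@beta, 0.25)
  withr::with_seed(12, {
    main <- rnorm(10, 0.2, 0.005)
    side <- rnorm(3, 0.8, 0.005)
  })
  theta <- c(main, side)
  h <- makeHarmonized(bx = rep(1, 13), by = theta, sy = rep(0.1, 13))
  fit <- weightedMode(h, n_boot = 50)
  bw <- 0.9 * min(weightedSd(theta, rep(1 / 13, 13)),
                  weightedMad(theta, rep(1 / 13, 13))) * 13^(-1 / 5)
  expect_lt(abs(fit@beta - 0.2), bw / 2 + 0.01)
  perm <- sample(13)
  h2 <- makeHarmonized(bx = rep(1, 13), by = theta[perm], sy = rep(0.1, 13))
  expect_equal(weightedMode(h2, n_boot = 50)@beta, fit@beta,
               tolerance = 1e-12)
})

test_that("odds-ratio conversion and round trip", {
  o0 <- toOddsRatio(0, 0.1)
  expect_equal(unname(o0["or"]), 1)
  expect_equal(unname(o0["ci_low"] * o0["ci_high"]), 1, tolerance = 1e-12)
  expect_equal(log(toOddsRatio(0.37, 0.1)[["or"]]), 0.37, tolerance = 1e-12)
})

test_that("estimators are invariant to SNP ordering", {
  withr::with_seed(15, {
    bx <- rnorm(20, 0, 0.05)
    by <- 0.2 * bx + rnorm(20, 0, 0.01)
    sy <- runif(20, 0.008, 0.02)
    perm <- sample(20)
  })
  h <- makeHarmonized(bx, by, sy)
  hp <- makeHarmonized(bx[perm], by[perm], sy[perm])
  expect_equal(mrIvw(h)$estimate@beta, mrIvw(hp)$estimate@beta,
               tolerance = 1e-12)
  expect_equal(mrEgger(h)$estimate@beta, mrEgger(hp)$estimate@beta,
               tolerance = 1e-12)
  expect_equal(weightedMedian(h, n_boot = 10)@beta,
               weightedMedian(hp, n_boot = 10)@beta, tolerance = 1e-12)
})
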