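COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complementAllele <- function(a) unname(COMPLEMENT[a])

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministically expand one master seed into n stage seeds, all < 2^31.
deriveSeeds <- function(master, n) {
  withr::with_seed(as.integer(master),
                   sample.int(.Machine$integer.max - 1L, n))
}

# Discrete weighted 0.5-quantile that respects atoms: the smallest value
# whose cumulative weight reaches 1/2; when the cumulative weight lands on
# 1/2 exactly, the two adjacent values are averaged (so equal weights give
# the plain median for both odd and even counts, and a value carrying more
# than half the weight is returned exactly).
weightedMedianAtom <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w)
  tol <- 1e-10
  i <- which(cw >= 0.5 - tol)[1]
  if (i < length(x) && abs(cw[i] - 0.5) <= tol) (x[i] + x[i + 1]) / 2 else x[i]
}

weightedSd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  sqrt(sum(w * (x - m)^2) / (1 - sum(w^2)))
}

weightedMad <- function(x, w) {
  med <- weightedMedianAtom(x, w)
  1.4826 * weightedMedianAtom(abs(x - med), w)
}
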