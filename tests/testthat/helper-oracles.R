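# Independent oracles used across the test files. These deliberately use
# brute-force / enumeration implementations, never the package's own code
# paths.

# AUC by direct pair counting with half-credit for ties
brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  s <- 0
  for (xi in x) for (yj in y)
    s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# DeLong variance of the AUC difference by explicit placement-value
# enumeration (double loops, explicit covariances)
brute_delong_var <- function(sa, sb, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos); n <- length(neg)
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- function(s) sapply(pos, function(i) mean(sapply(neg, function(j)
    psi(s[i], s[j]))))
  v01 <- function(s) sapply(neg, function(j) mean(sapply(pos, function(i)
    psi(s[i], s[j]))))
  a10 <- v10(sa); b10 <- v10(sb)
  a01 <- v01(sa); b01 <- v01(sb)
  (var(a10) + var(b10) - 2 * cov(a10, b10)) / m +
    (var(a01) + var(b01) - 2 * cov(a01, b01)) / n
}

# single-sided power fraction of a resampled signal by direct DFT
dft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  P <- Mod(fft(x))^2
  f <- (0:(n - 1)) * fs / n
  keep <- f > 0 & f <= fs / 2
  sum(P[keep & f >= lo & f < hi]) / sum(P[keep])
}

# a random positive RR series (ms) with occasional large jumps, as a
# beat_series
random_rr_series <- function(n, jump_prob = 0.1) {
  rr <- 1000 * exp(cumsum(rnorm(n, 0, 0.02)))
  jumps <- which(runif(n) < jump_prob)
  rr[jumps] <- rr[jumps] * sample(c(0.6, 1.5), length(jumps), replace = TRUE)
  beat_series(cumsum(rr) / 1000 - rr[1] / 1000, rr)
}

# three-covariate cohort configuration used when the fitted model must
# match the generative model exactly
cov3 <- list(
  dm = list(dist = "binary", p = 0.62),
  age10 = list(dist = "normal", mean = 5.48, sd = 1.3),
  ufr = list(dist = "normal", mean = 2.83, sd = 1.1, min = 0.2)
)
beta3 <- c("(Intercept)" = -1.5, dm = log(1.9), age10 = log(1.3),
           ufr = log(1.6))
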