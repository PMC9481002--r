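# Independent oracles, kept deliberately separate from the package's own
# implementations.

# literal scalar transcription of the two-cell formula
# -2 ln lambda = 2 sum_i O_i ln(O_i / E_i), E_i = N_i sum(O) / sum(N),
# written as a plain loop so it shares no code path with the package
ll_oracle <- function(a, b, n1, n2) {
  O <- c(a, b)
  N <- c(n1, n2)
  s <- 0
  for (i in 1:2) {
    e <- N[i] * sum(O) / sum(N)
    if (O[i] > 0) s <- s + O[i] * log(O[i] / e)
  }
  2 * s
}

# same statistic via a different algebraic expansion:
# 2*[a ln a + b ln b - (a+b) ln(a+b) + (a+b) ln N - a ln n1 - b ln n2].
# The big-term cancellation in this form costs ~1e-12 in absolute precision,
# so comparisons against it use an absolute tolerance.
ll_oracle_expanded <- function(a, b, n1, n2) {
  xlx <- function(x) if (x == 0) 0 else x * log(x)
  2 * (xlx(a) + xlx(b) - xlx(a + b) +
         (a + b) * log(n1 + n2) - a * log(n1) - b * log(n2))
}

# Welch's t from first-principles sums
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  v1 <- sum((x - m1)^2) / (n1 - 1)
  v2 <- sum((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Clopper-Pearson exact binomial confidence interval
exact_binom_ci <- function(k, n, conf = 0.99) {
  a <- (1 - conf) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}
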