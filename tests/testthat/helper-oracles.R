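# Independent brute-force oracles shared across test files.

# Passing-Bablok slope: plain double loop and explicit shifted median.
pb_oracle_slope <- function(a, b) {
  slopes <- c()
  n <- length(a)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- a[j] - a[i]; db <- b[j] - b[i]
    if (da == 0 && db == 0) next
    s <- if (da == 0) sign(db) * Inf else db / da
    if (s != -1) slopes <- c(slopes, s)
  }
  slopes <- sort(slopes)
  N <- length(slopes); K <- sum(slopes < -1)
  if (N %% 2 == 1) slopes[(N + 1) / 2 + K] else mean(slopes[N / 2 + K + 0:1])
}

# Exhaustive two-sided Mann-Whitney p by enumerating group assignments.
mw_oracle_p <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(g1, g2)
  us <- apply(combn(length(pooled), n1), 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  mu <- n1 * length(g2) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
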