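# Independent oracles shared across test files.

# two-sided Fisher p by direct enumeration of the hypergeometric
# distribution, summing outcomes no more probable than observed (with the
# conventional 1 + 1e-7 tie slack)
fisherOracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# plain-R dynamic-programming oracle for the optimal string alignment
# (restricted Damerau-Levenshtein) distance
osaOracle <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cost <- as.integer(a[i] != b[j])
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j])
      d[i + 1, j + 1] <- min(d[i + 1, j + 1], d[i - 1, j - 1] + 1L)
  }
  d[n + 1, m + 1]
}
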