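# Independent oracles, deliberately written against the definitions rather
# than against the package's code paths.

# Exhaustive Smith-Waterman-Gotoh score by dynamic programming over the full
# matrix, score only. Gap of length L costs open + (L - 1) * extend.
sw_oracle_score <- function(read, ref, match = 2, mismatch = -1,
                            gap_open = -2, gap_extend = -1) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  Fm <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open, E[i, j - 1] + gap_extend)
      Fm[i, j] <- max(H[i - 1, j] + gap_open, Fm[i - 1, j] + gap_extend)
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
    }
  }
  max(H)
}

# KL divergence by literal term-by-term summation.
kl_oracle <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) total <- total + p[i] * log(p[i] / q[i])
  total
}

# AUC as the proportion of (positive, negative) pairs ranked correctly,
# ties counting one half.
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Linear-interpolation quantile from the sorted array, written from the
# order-statistic definition: h = (n - 1) p + 1.
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

tukey_oracle <- function(x, k = 1.5) {
  q1 <- quantile_oracle(x, 0.25)
  q3 <- quantile_oracle(x, 0.75)
  q3 + k * (q3 - q1)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

random_simplex <- function(k) {
  x <- stats::rgamma(k, shape = 1) + 1e-6
  x / sum(x)
}
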