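# Independent brute-force oracles, deliberately naive implementations.

# Benjamini-Hochberg step-up, applied literally to the definition.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Kendall tau-b by explicit pair counting with tie corrections.
bruteForceTauB <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# AUC as the normalized Mann-Whitney U statistic with half-credit for ties.
bruteForceAUC <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Shared-partner counts by a triple loop over partners.
bruteForceSharedPartners <- function(M) {
  n <- nrow(M)
  A <- matrix(0L, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    A[i, k] <- sum(M[i, ] == 1 & M[k, ] == 1)
  }
  A
}
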