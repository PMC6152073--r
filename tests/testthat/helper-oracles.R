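# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the vectorized implementations they check.

# Bi-gram features by explicit triple loop over (m, n, i).
bigram_oracle <- function(P) {
  L <- nrow(P)
  v <- numeric(400L)
  for (m in 1:20) {
    for (n in 1:20) {
      acc <- 0
      if (L >= 2) {
        for (i in 1:(L - 1)) acc <- acc + P[i, m] * P[i + 1, n]
      }
      v[20 * (m - 1) + n] <- acc
    }
  }
  v
}

# Posterior moments by the textbook dense inverse.
posterior_oracle <- function(phi, t, alpha, sigma2) {
  A <- diag(alpha, ncol(phi))
  Sigma <- solve(t(phi) %*% phi / sigma2 + A)
  list(Sigma = Sigma, u = drop(Sigma %*% t(phi) %*% t) / sigma2)
}

# AUC as the Mann-Whitney pairwise count over all (positive, negative)
# score pairs, with half credit for ties.
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Kernel design matrix entry by entry.
design_oracle <- function(k, X, B) {
  out <- matrix(NA_real_, nrow(X), nrow(B) + 1L)
  for (i in seq_len(nrow(X))) {
    out[i, 1L] <- 1
    for (j in seq_len(nrow(B)))
      out[i, j + 1L] <- kernel_value(k, X[i, ], B[j, ])
  }
  out
}

# Blob training set matching centers (-3,-3) / (3,3), unit variance:
# class-mean distance 6*sqrt(2) over 2 dimensions.
blob_data <- function(n_per_class = 20, seed = 7) {
  gen_two_class_features(n_per_class, dim = 2L, separation = 6 * sqrt(2),
                         seed = seed)
}
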