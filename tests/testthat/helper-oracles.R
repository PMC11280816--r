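# Independent oracles used across tests.

# Brute-force same-padded 2-D filter response (double loop, zero padding,
# optional local mean removal) — independent of the package's index-gather
# implementation.
conv_oracle <- function(M, K, center = FALSE) {
  k1 <- nrow(K); k2 <- ncol(K)
  p1 <- (k1 - 1) %/% 2; p2 <- (k2 - 1) %/% 2
  P <- matrix(0, nrow(M) + 2 * p1, ncol(M) + 2 * p2)
  P[p1 + seq_len(nrow(M)), p2 + seq_len(ncol(M))] <- M
  out <- matrix(0, nrow(M), ncol(M))
  for (r in seq_len(nrow(M))) for (c in seq_len(ncol(M))) {
    patch <- P[r:(r + k1 - 1), c:(c + k2 - 1)]
    if (center) patch <- patch - mean(patch)
    out[r, c] <- sum(K * patch)
  }
  out
}

# A kernel that is 1 at the centre and 0 elsewhere (identity under
# same-padded filtering without centring).
delta_kernel <- function(k1, k2) {
  K <- matrix(0, k1, k2)
  K[(k1 + 1) %/% 2, (k2 + 1) %/% 2] <- 1
  K
}

# Small, fast model configuration used when a full pipeline must be fitted.
tiny_config <- function(...) {
  cobls_config(L1 = 4L, L2 = 4L, enh_width = 100L, ...)
}
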