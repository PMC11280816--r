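# Shared 2-D filtering machinery for the two convolutional layers.
#
# Feature maps are "same"-padded: the response at output pixel (r, c) is the
# inner product of the kernel with the zero-padded k1 x k2 neighbourhood
# centred at (r, c) (filter response / cross-correlation form). When
# `center = TRUE` the local neighbourhood mean is subtracted before the
# inner product, mirroring the per-patch centring used when the kernels were
# learned; without it, filter responses on raw ECG amplitudes are dominated
# by the local DC offset.

# Precompute gather indices mapping each output pixel's padded neighbourhood
# to positions in the zero-padded image vector (column-major everywhere).
same_pad_indices <- function(m, n, k1, k2) {
  p1 <- (k1 - 1L) %/% 2L
  p2 <- (k2 - 1L) %/% 2L
  pm <- m + 2L * p1
  pn <- n + 2L * p2
  base <- as.vector(outer(seq_len(k1), (seq_len(k2) - 1L) * pm, `+`))
  # output positions in column-major order; anchor of neighbourhood (r,c)
  # in the padded image is (r, c) (1-based) since the pad re-centres it
  shift <- as.vector(outer(seq_len(m) - 1L, (seq_len(n) - 1L) * pm, `+`))
  idx <- outer(base, shift, `+`)            # (k1*k2) x (m*n)
  interior <- as.vector(outer(p1 + seq_len(m), (p2 + seq_len(n) - 1L) * pm, `+`))
  list(idx = as.vector(idx), interior = interior, pm = pm, pn = pn)
}

# images: (m*n) x B matrix of column-major image vectors.
# kernels: L x (k1*k2) matrix of vectorised kernels.
# Returns L x (m*n*B): responses, image-major blocks with output pixels
# column-major within each image.
conv2_same_multi <- function(images, m, n, kernels, k1, k2, center = TRUE) {
  sp <- same_pad_indices(m, n, k1, k2)
  B <- ncol(images)
  padded <- matrix(0, sp$pm * sp$pn, B)
  padded[sp$interior, ] <- images
  P <- matrix(padded[sp$idx, , drop = FALSE], nrow = k1 * k2)
  if (center) P <- P - rep(colMeans(P), each = k1 * k2)
  kernels %*% P
}

# Single-image convenience wrapper returning an m x n response map.
conv2_same_one <- function(M, kernel, center = TRUE) {
  out <- conv2_same_multi(matrix(as.vector(M), ncol = 1L), nrow(M), ncol(M),
                          matrix(as.vector(kernel), nrow = 1L),
                          nrow(kernel), ncol(kernel), center = center)
  matrix(out, nrow(M), ncol(M))
}
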