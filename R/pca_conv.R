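#' Pool zero-mean patches from primary feature blocks
#'
#' Builds the second-layer pending matrix: stride-1 valid `k3 x k4` patches
#' from every map of every primary feature block, column-vectorised, each
#' patch centred to zero mean, concatenated column-wise.
#'
#' @param pfbs List of `primary_feature_block` objects (see
#'   [ica_convolve()]).
#' @param k3,k4 Patch dimensions (odd, no larger than the map dimensions).
#' @return Numeric `k3*k4 x n_patches` matrix.
#' @export
collect_secondary_patches <- function(pfbs, k3, k4) {
  if (length(pfbs) == 0L) stop("`pfbs` is empty")
  cols <- lapply(pfbs, function(pfb) {
    lapply(pfb$maps, function(M) extract_patches(M, k3, k4, center = TRUE)$patches)
  })
  do.call(cbind, unlist(cols, recursive = FALSE))
}

#' Learn the second-layer PCA convolution kernels
#'
#' Kernels are the unit eigenvectors of `U U^T` associated with the `L2`
#' largest eigenvalues, reshaped to `k3 x k4` with the patch vectorisation
#' order. The sign of each eigenvector is fixed so that its
#' largest-magnitude component is positive (eigenvectors are sign-ambiguous;
#' the convention makes refits reproducible).
#'
#' @param U Pooled patch matrix from [collect_secondary_patches()].
#' @param L2 Number of kernels (`<= k3*k4`).
#' @param k3,k4 Kernel dimensions.
#' @return A `pca_filter_bank`: list with `kernels`, `kernel_matrix`
#'   (`L2 x k3*k4`, orthonormal rows), `eigenvalues` (all, non-increasing),
#'   `k3`, `k4`, `L2`.
#' @export
fit_pca_filters <- function(U, L2, k3, k4) {
  U <- as.matrix(U)
  d <- nrow(U)
  if (d != k3 * k4) stop("nrow(U) must equal k3*k4")
  if (L2 > d) stop(sprintf("L2 = %d exceeds the patch dimension %d", L2, d))
  eg <- eigen(tcrossprod(U), symmetric = TRUE)
  vecs <- eg$vectors[, seq_len(L2), drop = FALSE]
  for (j in seq_len(L2)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  W <- t(vecs)
  kernels <- lapply(seq_len(L2), function(z) matrix(W[z, ], k3, k4))
  structure(list(kernels = kernels, kernel_matrix = W,
                 eigenvalues = eg$values, k3 = k3, k4 = k4, L2 = L2),
            class = "pca_filter_bank")
}

#' @export
print.pca_filter_bank <- function(x, ...) {
  cat(sprintf("<pca_filter_bank> %d kernels of %d x %d\n", x$L2, x$k3, x$k4))
  invisible(x)
}

#' Apply the PCA filter bank to a primary feature block
#'
#' Expands the full grid: every one of the `L1` primary maps is filtered by
#' every one of the `L2` kernels under the same same-padding and local
#' centring conventions as the first layer, giving `L1 * L2` secondary
#' feature maps.
#'
#' @param pfb A `primary_feature_block`.
#' @param bank A `pca_filter_bank`.
#' @param center Remove the local mean under each placement (default `TRUE`).
#' @return A `secondary_feature_block`: list `maps` indexed `[[l]][[zeta]]`.
#' @export
pca_convolve <- function(pfb, bank, center = TRUE) {
  stopifnot(inherits(pfb, "primary_feature_block"),
            inherits(bank, "pca_filter_bank"))
  maps <- lapply(pfb$maps, function(M) {
    out <- conv2_same_multi(matrix(as.vector(M), ncol = 1L), nrow(M), ncol(M),
                            bank$kernel_matrix, bank$k3, bank$k4,
                            center = center)
    lapply(seq_len(bank$L2), function(z) matrix(out[z, ], nrow(M), ncol(M)))
  })
  structure(list(maps = maps), class = "secondary_feature_block")
}
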