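#' Whitening transform for pooled beat patches
#'
#' Computes the covariance `C = X X^T` of the pooled patch matrix,
#' its eigendecomposition `C = E D E^T`, and the whitening matrix
#' `V = D_L1^{-1/2} E_L1^T` built from the `L1` largest eigenvalues, so that
#' `V C V^T` is the identity on the retained subspace. Eigenvalues below
#' `1e-12 * max(eigenvalue)` are floored there to guard rank-deficient
#' covariances.
#'
#' @param patches A `patch_set` (see [extract_patches()]) or a numeric
#'   `d x P` matrix of vectorised zero-mean patches in its columns.
#' @param L1 Number of whitened dimensions to retain (`<= d`).
#' @return A `whitening_model`: list with `V` (`L1 x d`), `eigenvalues`
#'   (all `d`, decreasing) and `C_rank` (count above the floor).
#' @export
compute_whitening <- function(patches, L1) {
  X <- if (inherits(patches, "patch_set")) patches$patches else as.matrix(patches)
  d <- nrow(X)
  if (L1 > d) stop(sprintf("L1 = %d exceeds the patch dimension %d", L1, d))
  if (ncol(X) < L1) stop("need at least L1 patches")
  if (all(X == 0)) stop("all-zero patch matrix: nothing to whiten")
  C <- tcrossprod(X)
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values
  floor_val <- 1e-12 * max(vals)
  C_rank <- sum(vals > floor_val)
  vals <- pmax(vals, floor_val)
  V <- (1 / sqrt(vals[seq_len(L1)])) * t(eg$vectors[, seq_len(L1), drop = FALSE])
  structure(list(V = V, eigenvalues = vals, C_rank = C_rank, d = d),
            class = "whitening_model")
}

ica_nonlinearity <- function(name) {
  switch(name,
    tanh  = list(g  = function(u) tanh(u),
                 dg = function(u) 1 - tanh(u)^2),
    gauss = list(g  = function(u) u * exp(-u^2 / 2),
                 dg = function(u) (1 - u^2) * exp(-u^2 / 2)),
    pow3  = list(g  = function(u) u^3,
                 dg = function(u) 3 * u^2),
    stop("unknown nonlinearity: ", name)
  )
}

sym_decorrelate <- function(W) {
  s <- eigen(tcrossprod(W), symmetric = TRUE)
  s$vectors %*% ((1 / sqrt(pmax(s$values, 1e-300))) * t(s$vectors)) %*% W
}

#' Fixed-point FastICA unmixing on whitened patches
#'
#' Symmetric (parallel) fixed-point ICA: all `L1` components are updated
#' jointly and re-orthonormalised by symmetric decorrelation each iteration.
#' The data are assumed whitened (approximately identity covariance), so the
#' unmixing estimate `B` has orthonormal rows. Deterministic given `seed`.
#' On non-convergence the current iterate is returned with a warning (never
#' an error).
#'
#' @param whitened `L1 x N` matrix of whitened observations.
#' @param L1 Number of components (defaults to `nrow(whitened)`).
#' @param nonlinearity Contrast function: `"tanh"` (default), `"gauss"` or
#'   `"pow3"`.
#' @param seed Integer seed for the random initial matrix.
#' @param max_iter,tol Fixed-point iteration cap (200) and convergence
#'   tolerance (1e-4) on the rotation invariance of successive iterates.
#' @return `L1 x L1` matrix `B` with orthonormal rows.
#' @export
fit_ica_unmixing <- function(whitened, L1 = nrow(whitened),
                             nonlinearity = c("tanh", "gauss", "pow3"),
                             seed = 1L, max_iter = 200L, tol = 1e-4) {
  nonlinearity <- match.arg(nonlinearity)
  X <- as.matrix(whitened)
  if (nrow(X) != L1) stop("`whitened` must have L1 rows")
  N <- ncol(X)
  # The whitening convention V C V^T = I with C = X X^T leaves the whitened
  # rows at unit norm rather than unit variance; rescale to unit mean square
  # so the contrast nonlinearity operates in its informative range. B is a
  # rotation estimate and is unaffected by a global scale.
  ms <- mean(X^2)
  if (ms > 0) X <- X / sqrt(ms)
  nl <- ica_nonlinearity(nonlinearity)
  W <- withr::with_seed(seed, matrix(stats::rnorm(L1 * L1), L1, L1))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- W %*% X
    G <- nl$g(U)
    W1 <- tcrossprod(G, X) / N - rowMeans(nl$dg(U)) * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("FastICA did not converge in %d iterations (delta %.2e); returning current iterate",
                    max_iter, delta))
  attr(W, "nonlinearity") <- nonlinearity
  attr(W, "converged") <- converged
  W
}

#' Assemble the first-layer ICA convolution kernels
#'
#' Kernel `l` is row `l` of `B V` reshaped to `k1 x k2` with the same
#' column-major element order used to vectorise patches, so
#' `as.vector(kernel_l)` recovers the row exactly.
#'
#' @param B `L1 x L1` orthonormal unmixing matrix (see [fit_ica_unmixing()]).
#' @param whitening A `whitening_model` from [compute_whitening()].
#' @param k1,k2 Kernel dimensions; `k1 * k2` must equal the patch dimension.
#' @param seed Seed recorded for provenance.
#' @return An `ica_filter_bank`: list with `kernels` (list of `k1 x k2`
#'   matrices), `kernel_matrix` (`L1 x k1*k2`), `B`, `nonlinearity`, `seed`,
#'   `k1`, `k2`, `L1`.
#' @export
build_ica_filters <- function(B, whitening, k1, k2, seed = NA_integer_) {
  stopifnot(inherits(whitening, "whitening_model"))
  if (ncol(whitening$V) != k1 * k2)
    stop(sprintf("whitening dimension %d does not match k1*k2 = %d",
                 ncol(whitening$V), k1 * k2))
  if (ncol(B) != nrow(whitening$V))
    stop("B and whitening matrix shapes do not conform")
  W <- B %*% whitening$V
  kernels <- lapply(seq_len(nrow(W)), function(l) matrix(W[l, ], k1, k2))
  structure(list(kernels = kernels, kernel_matrix = W, B = B,
                 nonlinearity = attr(B, "nonlinearity") %||% NA_character_,
                 seed = seed, k1 = k1, k2 = k2, L1 = nrow(W)),
            class = "ica_filter_bank")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ica_filter_bank <- function(x, ...) {
  cat(sprintf("<ica_filter_bank> %d kernels of %d x %d (%s nonlinearity)\n",
              x$L1, x$k1, x$k2,
              ifelse(is.na(x$nonlinearity), "?", x$nonlinearity)))
  invisible(x)
}

#' Apply the ICA filter bank to one beat matrix
#'
#' Same-padded 2-D filtering: each of the `L1` kernels produces a response
#' map with the spatial shape of the input (the primary feature block). With
#' `center = TRUE` (default) the local patch mean under each kernel placement
#' is removed first, mirroring the training-patch centring.
#'
#' @param M Beat matrix (e.g. from [beat_to_matrix()]).
#' @param bank An `ica_filter_bank`.
#' @param center Remove the local mean under each placement.
#' @return A `primary_feature_block`: list of `L1` response maps.
#' @export
ica_convolve <- function(M, bank, center = TRUE) {
  stopifnot(inherits(bank, "ica_filter_bank"))
  out <- conv2_same_multi(matrix(as.vector(M), ncol = 1L), nrow(M), ncol(M),
                          bank$kernel_matrix, bank$k1, bank$k2, center = center)
  maps <- lapply(seq_len(bank$L1),
                 function(l) matrix(out[l, ], nrow(M), ncol(M)))
  structure(list(maps = maps), class = "primary_feature_block")
}
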