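#' Heaviside binarisation
#'
#' Elementwise step function used to hash filter responses: strictly
#' positive values map to 1, zero and negative values map to 0.
#'
#' @param x Numeric vector, matrix or array.
#' @return Integer object of the same shape with entries in \{0, 1\}.
#' @export
heaviside <- function(x) {
  out <- (x > 0) * 1L
  out
}

#' Combine binary maps into a decimal ("grayscale") image
#'
#' The ordered binary maps are summed with power-of-two weights:
#' `T = sum_z 2^(z-1) * map_z`, so each pixel is an integer code in
#' `[0, 2^levels - 1]` where `levels` is the number of maps.
#'
#' @param binary_maps List of equal-shaped 0/1 matrices, ordered by filter
#'   index (weight `2^(z-1)` for the z-th map).
#' @return A `decimal_image`: integer matrix with attribute `levels`.
#' @export
decimal_encode <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1L)
  dims <- dim(binary_maps[[1L]])
  for (m in binary_maps)
    if (!identical(dim(m), dims)) stop("binary maps must all have the same shape")
  T_img <- Reduce(`+`, Map(function(m, z) (2^(z - 1)) * m,
                           binary_maps, seq_along(binary_maps)))
  structure(T_img, levels = length(binary_maps), class = "decimal_image")
}

# Anchor positions for overlapping blocks along one dimension:
# stride = round(block * (1 - overlap)); the final block is clamped to the
# border so every pixel is covered.
block_anchors <- function(dim, block, overlap) {
  if (block > dim) stop("block does not fit inside the image")
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)")
  stride <- round(block * (1 - overlap))
  if (stride < 1) stop("degenerate stride 0: reduce `overlap` or enlarge the block")
  a <- seq(1L, dim - block + 1L, by = stride)
  last <- dim - block + 1L
  if (a[length(a)] != last) a <- c(a, last)
  as.integer(a)
}

#' Overlapping block histograms of a decimal image
#'
#' Blocks tile the image at stride `round(block * (1 - overlap))`; a final
#' clamped block is appended along each axis when the regular grid leaves
#' border pixels uncovered. Each block contributes one count histogram over
#' the code values `0 ... 2^levels - 1`.
#'
#' @param T_img A `decimal_image` (see [decimal_encode()]) or an integer
#'   matrix (then `levels` must be supplied).
#' @param block_h,block_w Block height and width.
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param levels Number of binary maps combined into `T_img` (bins =
#'   `2^levels`); taken from the `decimal_image` attribute when present.
#' @return Integer `p x 2^levels` matrix; rows are blocks in row-major
#'   anchor order, each row sums to its block's pixel count.
#' @export
block_histograms <- function(T_img, block_h = 7L, block_w = 7L, overlap = 0.5,
                             levels = attr(T_img, "levels")) {
  if (is.null(levels)) stop("`levels` must be given for a plain matrix")
  nbins <- 2L^levels
  m <- nrow(T_img); n <- ncol(T_img)
  ar <- block_anchors(m, block_h, overlap)
  ac <- block_anchors(n, block_w, overlap)
  p <- length(ar) * length(ac)
  H <- matrix(0L, p, nbins)
  b <- 0L
  for (r in ar) for (cc in ac) {
    b <- b + 1L
    blk <- T_img[r:(r + block_h - 1L), cc:(cc + block_w - 1L)]
    H[b, ] <- tabulate(as.integer(blk) + 1L, nbins = nbins)
  }
  H
}

#' Encode one beat's secondary feature grid into the feature vector
#'
#' For each of the `L1` primary maps, its `L2` secondary maps are Heaviside
#' binarised and combined into one decimal image; all block histograms are
#' concatenated in (primary map, block, bin) order — bin index fastest,
#' then block, then primary map — into the per-beat feature vector `f`.
#'
#' @param sfb A `secondary_feature_block` (full `L1 x L2` grid from
#'   [pca_convolve()]).
#' @param block_h,block_w,overlap Histogram block geometry (see
#'   [block_histograms()]).
#' @param normalize Divide each block histogram by its pixel count
#'   (default `FALSE`: raw counts).
#' @return Numeric feature vector of length `L1 * p * 2^L2`.
#' @export
encode_beat <- function(sfb, block_h = 7L, block_w = 7L, overlap = 0.5,
                        normalize = FALSE) {
  stopifnot(inherits(sfb, "secondary_feature_block"))
  L2 <- length(sfb$maps[[1L]])
  for (l in seq_along(sfb$maps))
    if (length(sfb$maps[[l]]) != L2) stop("incomplete secondary feature grid")
  parts <- lapply(sfb$maps, function(secondary) {
    T_img <- decimal_encode(lapply(secondary, heaviside))
    H <- block_histograms(T_img, block_h, block_w, overlap)
    if (normalize) H <- H / rowSums(H)
    as.vector(t(H))                      # bin fastest, then block
  })
  unlist(parts, use.names = FALSE)
}

# Vectorised encoder used by the model: beats (B x 300) -> features (B x D).
# Identical output to the per-beat path (ica_convolve -> pca_convolve ->
# encode_beat), computed with batched index-gather convolutions; memory is
# bounded by chunking over beats.
encode_features <- function(X, ica_bank, pca_bank,
                            block_h = 7L, block_w = 7L, overlap = 0.5,
                            normalize = FALSE, center = TRUE,
                            nrow_img = 20L, ncol_img = 15L,
                            order = "row", chunk = 128L) {
  X <- as.matrix(X)
  B <- nrow(X)
  m <- nrow_img; n <- ncol_img
  L1 <- ica_bank$L1; L2 <- pca_bank$L2
  nbins <- 2L^L2
  # permutation: column-major image position -> sample index under the
  # configured beat-matrix fill order
  if (order == "row") {
    rr <- rep(seq_len(m), times = n)
    cc <- rep(seq_len(n), each = m)
    perm <- (rr - 1L) * n + cc
  } else {
    perm <- seq_len(m * n)
  }
  # block pixel expansion for one column-major image
  ar <- block_anchors(m, block_h, overlap)
  ac <- block_anchors(n, block_w, overlap)
  p <- length(ar) * length(ac)
  blockpix <- integer(0); blockid <- integer(0); bi <- 0L
  for (r in ar) for (c0 in ac) {
    bi <- bi + 1L
    pix <- as.vector(outer(r:(r + block_h - 1L), (c0:(c0 + block_w - 1L) - 1L) * m, `+`))
    blockpix <- c(blockpix, pix)
    blockid <- c(blockid, rep(bi, length(pix)))
  }
  block_px_count <- block_h * block_w
  D <- L1 * p * nbins
  weights <- 2^(seq_len(L2) - 1L)
  out <- matrix(0, B, D)
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    nb <- length(idx)
    images <- t(X[idx, , drop = FALSE])[perm, , drop = FALSE]   # (m*n) x nb
    Z1 <- conv2_same_multi(images, m, n, ica_bank$kernel_matrix,
                           ica_bank$k1, ica_bank$k2, center = center)
    # L1 x (m*n*nb) -> maps as columns ordered (l fastest, then beat)
    maps1 <- matrix(aperm(array(Z1, c(L1, m * n, nb)), c(2L, 1L, 3L)),
                    nrow = m * n)
    Z2 <- conv2_same_multi(maps1, m, n, pca_bank$kernel_matrix,
                           pca_bank$k3, pca_bank$k4, center = center)
    Tcodes <- as.vector(weights %*% (Z2 > 0))       # length m*n*L1*nb
    Tm <- matrix(Tcodes, nrow = m * n)              # cols: (l, beat)
    V <- Tm[blockpix, , drop = FALSE]
    code <- V + nbins * (blockid - 1L)              # recycles down columns
    ncells <- ncol(V)
    global <- as.vector(code) + (nbins * p) * rep(seq_len(ncells) - 1L,
                                                  each = length(blockpix))
    counts <- tabulate(global + 1L, nbins = nbins * p * ncells)
    F_chunk <- matrix(counts, nrow = D, ncol = nb)
    if (normalize) F_chunk <- F_chunk / block_px_count
    out[idx, ] <- t(F_chunk)
  }
  out
}
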