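#' Segment an annotated ECG signal into fixed-length beats
#'
#' Cuts one 300-sample window around every annotated R-peak: 149 samples
#' before the peak and 150 after it (the peak itself sits at position 150 of
#' the beat, 1-based). Annotation symbols are mapped to AAMI superclasses via
#' [map_aami()]; beats mapping to Q, to non-beat annotations, or whose window
#' crosses a record boundary are dropped.
#'
#' @param signal Numeric vector, single-lead ECG amplitudes (physical units).
#' @param r_peaks Integer vector of annotated R-peak sample indices (1-based),
#'   sorted ascending.
#' @param symbols Character vector of annotation symbols, same length as
#'   `r_peaks`.
#' @param pre,post Number of samples kept before/after the R-peak
#'   (defaults 149/150, i.e. 300-sample beats at 360 Hz).
#' @return A list of `heartbeat` objects, each with fields `samples`
#'   (length `pre + post + 1`), `label` (one of `"N","S","V","F"`) and
#'   `r_index` (R-peak index in `signal`).
#' @seealso [beat_to_matrix()], [map_aami()]
#' @export
segment_beats <- function(signal, r_peaks, symbols, pre = 149L, post = 150L) {
  if (length(signal) == 0L) stop("`signal` is empty")
  if (length(r_peaks) != length(symbols))
    stop("`r_peaks` and `symbols` must have the same length")
  if (is.unsorted(r_peaks, strictly = FALSE))
    stop("`r_peaks` must be sorted in ascending order")
  classes <- map_aami(symbols)
  keep <- classes %in% c("N", "S", "V", "F")
  r_peaks <- r_peaks[keep]
  classes <- classes[keep]
  n <- length(signal)
  in_bounds <- (r_peaks - pre) >= 1L & (r_peaks + post) <= n
  n_dropped <- sum(!in_bounds)
  if (n_dropped > 0L)
    message(n_dropped, " beat(s) dropped: window crosses the record boundary")
  r_peaks <- r_peaks[in_bounds]
  classes <- classes[in_bounds]
  beats <- vector("list", length(r_peaks))
  for (i in seq_along(r_peaks)) {
    r <- r_peaks[i]
    beats[[i]] <- new_heartbeat(signal[(r - pre):(r + post)], classes[i], r)
  }
  beats
}

new_heartbeat <- function(samples, label, r_index) {
  structure(list(samples = as.numeric(samples), label = label,
                 r_index = as.integer(r_index)),
            class = "heartbeat")
}

#' @export
print.heartbeat <- function(x, ...) {
  cat(sprintf("<heartbeat> %d samples, class %s, R-peak at sample %d\n",
              length(x$samples), x$label, x$r_index))
  invisible(x)
}

#' Stack a list of heartbeats into a beats-by-samples matrix
#'
#' @param beats List of `heartbeat` objects (see [segment_beats()]).
#' @return A list with `X` (numeric matrix, one beat per row) and `labels`
#'   (factor of AAMI classes).
#' @export
beat_stack <- function(beats) {
  stopifnot(length(beats) > 0L)
  X <- t(vapply(beats, function(b) b$samples, numeric(length(beats[[1L]]$samples))))
  labels <- factor(vapply(beats, function(b) b$label, character(1L)))
  list(X = X, labels = labels)
}

#' Reshape a 300-sample beat into its 20 x 15 matrix form
#'
#' The 1-D beat is rearranged into a 2-D pseudo-image so that the cascaded
#' convolution layers see a larger receptive field. The default fill is
#' row-major: matrix element (r, c) holds sample 15 (r - 1) + c, so each row
#' keeps 15 consecutive samples (short-time locality). Column-major fill is
#' available for replication experiments.
#'
#' @param beat A `heartbeat` or a numeric vector whose length is
#'   `nrow * ncol`.
#' @param nrow,ncol Matrix dimensions (default 20 x 15).
#' @param order `"row"` (default) or `"col"` fill order.
#' @return Numeric `nrow x ncol` matrix; the source beat (if a `heartbeat`
#'   was given) is kept in attribute `"source"`.
#' @export
beat_to_matrix <- function(beat, nrow = 20L, ncol = 15L, order = c("row", "col")) {
  order <- match.arg(order)
  samples <- if (inherits(beat, "heartbeat")) beat$samples else as.numeric(beat)
  if (length(samples) != nrow * ncol)
    stop(sprintf("beat has %d samples; expected %d (= %d x %d)",
                 length(samples), nrow * ncol, nrow, ncol))
  M <- matrix(samples, nrow = nrow, ncol = ncol, byrow = (order == "row"))
  if (inherits(beat, "heartbeat")) attr(M, "source") <- beat
  M
}

#' Flatten a beat matrix back to the sample vector
#'
#' Inverse of [beat_to_matrix()] under the same fill order; the round trip is
#' bit-exact.
#'
#' @param M Numeric matrix.
#' @param order Fill order used to build `M`.
#' @return Numeric vector of length `nrow(M) * ncol(M)`.
#' @export
matrix_to_beat <- function(M, order = c("row", "col")) {
  order <- match.arg(order)
  if (order == "row") as.vector(t(M)) else as.vector(M)
}

#' Extract dense zero-mean patches from a beat matrix
#'
#' Stride-1 "valid" block sampling: one k1 x k2 patch per anchor position,
#' (rows - k1 + 1)(cols - k2 + 1) patches in total. Each patch is
#' column-vectorised (column-major within the patch) and its own mean is
#' removed, matching the centring convention under which the convolution
#' kernels are learned.
#'
#' @param M Numeric matrix (e.g. a 20 x 15 beat matrix or a feature map).
#' @param k1,k2 Patch height and width; both must be odd and no larger than
#'   the matrix dimensions.
#' @param center Subtract each patch's mean (default `TRUE`).
#' @return A `patch_set`: list with `patches` (`k1*k2 x n_patches` matrix,
#'   anchors in row-major raster order), `positions` (two-column matrix of
#'   1-based top-left anchors) and `k1`, `k2`.
#' @export
extract_patches <- function(M, k1, k2, center = TRUE) {
  m <- nrow(M); n <- ncol(M)
  if (k1 %% 2L == 0L || k2 %% 2L == 0L)
    stop("patch dimensions k1, k2 must be odd")
  if (k1 > m || k2 > n)
    stop(sprintf("patch %dx%d does not fit inside a %dx%d matrix", k1, k2, m, n))
  anchors_r <- seq_len(m - k1 + 1L)
  anchors_c <- seq_len(n - k2 + 1L)
  # raster order: sweep columns within each row of anchors
  pos <- cbind(row = rep(anchors_r, each = length(anchors_c)),
               col = rep(anchors_c, times = length(anchors_r)))
  # linear indices of one patch at anchor (1,1), column-major within patch
  base <- as.vector(outer(seq_len(k1), (seq_len(k2) - 1L) * m, `+`))
  shift <- (pos[, "row"] - 1L) + (pos[, "col"] - 1L) * m
  idx <- outer(base, shift, `+`)            # (k1*k2) x n_patches
  P <- matrix(M[idx], nrow = k1 * k2)
  if (center) P <- sweep(P, 2L, colMeans(P), `-`)
  structure(list(patches = P, positions = pos, k1 = k1, k2 = k2),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d\n",
              ncol(x$patches), x$k1, x$k2))
  invisible(x)
}

# Pool valid, centred patches from many images given as columns of a
# samples-by-images matrix (column-major image layout). Returns d x (P*B).
pool_patches <- function(images, m, n, k1, k2) {
  anchors_r <- seq_len(m - k1 + 1L)
  anchors_c <- seq_len(n - k2 + 1L)
  base <- as.vector(outer(seq_len(k1), (seq_len(k2) - 1L) * m, `+`))
  shift <- as.vector(outer((anchors_r - 1L),
                           (anchors_c - 1L) * m, `+`)) # col-major anchor order
  idx <- as.vector(outer(base, shift, `+`))
  B <- ncol(images)
  P <- matrix(images[idx, , drop = FALSE], nrow = k1 * k2)
  P - rep(colMeans(P), each = k1 * k2)
}
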