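#' Configuration for a COBLS model
#'
#' Collects every tunable of the pipeline with the published defaults:
#' 7 x 7 kernels in both convolution layers, `L1 = L2 = 8` filters
#' (decimal codes in `[0, 255]`), 7 x 7 histogram blocks with 50% overlap,
#' and a single group of 9000 tanh enhancement nodes. The ridge parameter,
#' weight shrink and activation are declared defaults (`lambda = 1e-8`,
#' `s = 0.8`, tanh).
#'
#' @param k1,k2 First-layer (ICA) kernel dimensions (odd).
#' @param k3,k4 Second-layer (PCA) kernel dimensions (odd).
#' @param L1,L2 Number of ICA / PCA kernels.
#' @param nonlinearity FastICA contrast: `"tanh"`, `"gauss"` or `"pow3"`.
#' @param block_h,block_w,overlap Histogram block geometry.
#' @param hist_normalize Per-block L1 normalisation of histograms
#'   (default `FALSE`: raw counts).
#' @param m Number of enhancement-node groups.
#' @param enh_width Nodes per enhancement group.
#' @param shrink Scale `s` applied to the random enhancement weights.
#' @param activation Enhancement activation: `"tanh"` (default), `"sigmoid"`
#'   or `"relu"`.
#' @param lambda Ridge regularisation parameter (>= 0).
#' @param standardize Standardise the histogram features with training-fold
#'   mean/sd before the head (default `TRUE`; ridge on raw counts is
#'   scale-dominated).
#' @param center Mirror training-patch centring at inference by removing the
#'   local mean under each kernel placement (default `TRUE`).
#' @param encoder `"cobls"` (cascaded convolutional features) or `"raw"`
#'   (flattened beat samples — the plain-BLS baseline).
#' @param ica_max_iter,ica_tol FastICA iteration cap and tolerance.
#' @param reshape_order Beat-matrix fill order, `"row"` or `"col"`.
#' @param filter_beats Optional cap on the number of training beats pooled
#'   for filter learning (`NULL` = use all).
#' @return A `cobls_config` list.
#' @export
cobls_config <- function(k1 = 7L, k2 = 7L, k3 = 7L, k4 = 7L,
                         L1 = 8L, L2 = 8L,
                         nonlinearity = c("tanh", "gauss", "pow3"),
                         block_h = 7L, block_w = 7L, overlap = 0.5,
                         hist_normalize = FALSE,
                         m = 1L, enh_width = 9000L, shrink = 0.8,
                         activation = c("tanh", "sigmoid", "relu"),
                         lambda = 1e-8, standardize = TRUE, center = TRUE,
                         encoder = c("cobls", "raw"),
                         ica_max_iter = 200L, ica_tol = 1e-4,
                         reshape_order = c("row", "col"),
                         filter_beats = NULL) {
  cfg <- list(k1 = as.integer(k1), k2 = as.integer(k2),
              k3 = as.integer(k3), k4 = as.integer(k4),
              L1 = as.integer(L1), L2 = as.integer(L2),
              nonlinearity = match.arg(nonlinearity),
              block_h = as.integer(block_h), block_w = as.integer(block_w),
              overlap = overlap, hist_normalize = hist_normalize,
              m = as.integer(m), enh_width = as.integer(enh_width),
              shrink = shrink, activation = match.arg(activation),
              lambda = lambda, standardize = standardize, center = center,
              encoder = match.arg(encoder),
              ica_max_iter = as.integer(ica_max_iter), ica_tol = ica_tol,
              reshape_order = match.arg(reshape_order),
              filter_beats = filter_beats)
  stopifnot(cfg$k1 %% 2L == 1L, cfg$k2 %% 2L == 1L,
            cfg$k3 %% 2L == 1L, cfg$k4 %% 2L == 1L,
            cfg$L1 >= 1L, cfg$L2 >= 1L, cfg$lambda >= 0,
            cfg$m >= 1L, cfg$enh_width >= 1L, cfg$shrink >= 0,
            cfg$overlap >= 0, cfg$overlap < 1)
  if (cfg$L1 > cfg$k1 * cfg$k2)
    stop("L1 may not exceed k1*k2")
  if (cfg$L2 > cfg$k3 * cfg$k4)
    stop("L2 may not exceed k3*k4")
  structure(cfg, class = "cobls_config")
}

activation_fun <- function(name) {
  switch(name,
    tanh    = tanh,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    relu    = function(x) pmax(x, 0),
    stop("unknown activation: ", name))
}

#' Initialise random enhancement-node weights
#'
#' Entries are drawn i.i.d. uniform on \[-1, 1\] from the seeded generator
#' and scaled by the shrink `s`; deterministic given `seed`.
#'
#' @param n_features Input dimension (number of feature nodes).
#' @param m Number of groups.
#' @param group_width Nodes per group.
#' @param seed Integer seed.
#' @param s Shrink scale applied to weights and biases.
#' @return List with `W_h` (list of `n_features x group_width` matrices) and
#'   `beta_h` (list of length-`group_width` bias vectors).
#' @export
init_enhancement <- function(n_features, m = 1L, group_width = 9000L,
                             seed = 1L, s = 0.8) {
  stopifnot(n_features >= 1L, m >= 1L, group_width >= 1L)
  withr::with_seed(seed, {
    W_h <- vector("list", m)
    beta_h <- vector("list", m)
    for (j in seq_len(m)) {
      W_h[[j]] <- matrix(stats::runif(n_features * group_width, -1, 1),
                         n_features, group_width) * s
      beta_h[[j]] <- stats::runif(group_width, -1, 1) * s
    }
    list(W_h = W_h, beta_h = beta_h)
  })
}

#' Compute the enhancement-node activations
#'
#' `H_j = xi(Z W_hj + beta_hj)` for each group j, concatenated column-wise.
#'
#' @param Z `N x n_features` feature-node matrix.
#' @param W_h,beta_h Lists from [init_enhancement()].
#' @param activation Activation name (default `"tanh"`).
#' @return `N x (m * group_width)` matrix.
#' @export
compute_enhancement <- function(Z, W_h, beta_h, activation = "tanh") {
  xi <- activation_fun(activation)
  blocks <- Map(function(W, b) {
    if (nrow(W) != ncol(Z)) stop("Z column count does not match W_h rows")
    xi(sweep(Z %*% W, 2L, b, `+`))
  }, W_h, beta_h)
  do.call(cbind, blocks)
}

#' Closed-form ridge solution for the output weights
#'
#' Solves the regularised normal equations
#' `(lambda I + A^T A) W = A^T Y` by a stable Cholesky solve, never by an
#' explicit inverse. When `A` has more columns than rows the equivalent dual
#' identity `W = A^T (lambda I + A A^T)^{-1} Y` is used. For `lambda = 0` a
#' full-column-rank least-squares solve (the Moore-Penrose solution) is
#' returned; rank-deficient `A` with `lambda = 0` raises an error asking for
#' a positive `lambda`.
#'
#' @param A `N x d` expanded matrix `[Z | H]`.
#' @param Y `N x L` one-hot (or real) target matrix.
#' @param lambda Ridge parameter, `>= 0`.
#' @return `d x L` weight matrix.
#' @export
ridge_weights <- function(A, Y, lambda = 1e-8) {
  A <- as.matrix(A); Y <- as.matrix(Y)
  if (nrow(A) != nrow(Y)) stop("A and Y must have the same number of rows")
  if (lambda < 0) stop("`lambda` must be non-negative")
  if (lambda == 0) {
    qa <- qr(A)
    if (qa$rank < ncol(A))
      stop("A is rank-deficient: use a positive `lambda` for the ridge solution")
    return(qr.coef(qa, Y))
  }
  if (ncol(A) <= nrow(A)) {
    M <- crossprod(A)
    diag(M) <- diag(M) + lambda
    ch <- chol(M)
    backsolve(ch, forwardsolve(t(ch), crossprod(A, Y)))
  } else {
    G <- tcrossprod(A)
    diag(G) <- diag(G) + lambda
    ch <- chol(G)
    crossprod(A, backsolve(ch, forwardsolve(t(ch), Y)))
  }
}

one_hot <- function(labels, class_order) {
  Y <- matrix(0, length(labels), length(class_order))
  Y[cbind(seq_along(labels), match(as.character(labels), class_order))] <- 1
  Y
}

fit_scaler <- function(F_mat) {
  mu <- colMeans(F_mat)
  sdv <- apply(F_mat, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(F_mat, scaler) {
  (F_mat - rep(scaler$mean, each = nrow(F_mat))) /
    rep(scaler$sd, each = nrow(F_mat))
}

#' Fit a COBLS classifier
#'
#' Runs the full training procedure: pool zero-mean patches from the
#' training beat matrices, learn the whitening + FastICA kernels, produce
#' the primary feature blocks, learn the PCA kernels from their patches,
#' produce the secondary blocks, hash them into block-histogram feature
#' vectors `f` (the feature nodes), standardise, generate the random
#' enhancement nodes and solve the ridge output weights in closed form.
#' All randomness derives from `seed` (FastICA initialisation uses
#' `seed`, the enhancement weights `seed + 1`).
#'
#' @param X `N x 300` beat matrix (one beat per row) or a list of
#'   `heartbeat` objects; when beats are given, `labels` defaults to their
#'   AAMI labels.
#' @param labels Class labels (factor or character), length `N`; at least
#'   two classes must be present.
#' @param config A [cobls_config()].
#' @param seed Integer master seed.
#' @return A `cobls_model` with the frozen filter banks, coding config,
#'   feature scaler, enhancement weights, output weights `Wnm` and the
#'   fixed `class_order`.
#' @export
cobls_fit <- function(X, labels = NULL, config = cobls_config(), seed = 1L) {
  stopifnot(inherits(config, "cobls_config"))
  if (is.list(X) && !is.matrix(X) && inherits(X[[1L]], "heartbeat")) {
    st <- beat_stack(X)
    if (is.null(labels)) labels <- st$labels
    X <- st$X
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("labels length must match the number of beats")
  class_order <- sort(unique(labels))
  if (length(class_order) < 2L)
    stop("training set contains a single class; at least two are required")

  banks <- NULL
  if (config$encoder == "cobls") {
    banks <- learn_filter_banks(X, config, seed = seed)
    F_mat <- encode_features(X, banks$ica, banks$pca,
                             block_h = config$block_h, block_w = config$block_w,
                             overlap = config$overlap,
                             normalize = config$hist_normalize,
                             center = config$center,
                             order = config$reshape_order)
  } else {
    F_mat <- X
  }
  scaler <- if (config$standardize) fit_scaler(F_mat) else NULL
  Z <- if (is.null(scaler)) F_mat else apply_scaler(F_mat, scaler)
  enh <- init_enhancement(ncol(Z), m = config$m, group_width = config$enh_width,
                          seed = seed + 1L, s = config$shrink)
  H <- compute_enhancement(Z, enh$W_h, enh$beta_h, config$activation)
  A <- cbind(Z, H)
  Y <- one_hot(labels, class_order)
  Wnm <- ridge_weights(A, Y, config$lambda)
  structure(list(ica_bank = banks$ica, pca_bank = banks$pca,
                 scaler = scaler, W_h = enh$W_h, beta_h = enh$beta_h,
                 Wnm = Wnm, class_order = class_order,
                 config = config, seed = as.integer(seed)),
            class = "cobls_model")
}

# Learn both filter banks from training beats (internal).
learn_filter_banks <- function(X, config, seed) {
  Xf <- X
  if (!is.null(config$filter_beats) && nrow(X) > config$filter_beats)
    Xf <- X[withr::with_seed(seed + 2L,
                             sample.int(nrow(X), config$filter_beats)), ,
            drop = FALSE]
  m <- 20L; n <- 15L
  if (ncol(Xf) != m * n)
    stop(sprintf("beats must have %d samples", m * n))
  # column-major image vectors under the configured reshape order
  if (config$reshape_order == "row") {
    rr <- rep(seq_len(m), times = n); cc <- rep(seq_len(n), each = m)
    perm <- (rr - 1L) * n + cc
    images <- t(Xf)[perm, , drop = FALSE]
  } else {
    images <- t(Xf)
  }
  P1 <- pool_patches(images, m, n, config$k1, config$k2)
  wh <- compute_whitening(P1, config$L1)
  B <- fit_ica_unmixing(wh$V %*% P1, L1 = config$L1,
                        nonlinearity = config$nonlinearity, seed = seed,
                        max_iter = config$ica_max_iter, tol = config$ica_tol)
  ica_bank <- build_ica_filters(B, wh, config$k1, config$k2, seed = seed)
  Z1 <- conv2_same_multi(images, m, n, ica_bank$kernel_matrix,
                         config$k1, config$k2, center = config$center)
  maps1 <- matrix(aperm(array(Z1, c(config$L1, m * n, ncol(images))),
                        c(2L, 1L, 3L)), nrow = m * n)
  U <- pool_patches(maps1, m, n, config$k3, config$k4)
  pca_bank <- fit_pca_filters(U, config$L2, config$k3, config$k4)
  list(ica = ica_bank, pca = pca_bank, whitening = wh)
}

#' @export
print.cobls_model <- function(x, ...) {
  cat(sprintf("<cobls_model> %s encoder, classes: %s\n",
              x$config$encoder, paste(x$class_order, collapse = ", ")))
  if (!is.null(x$ica_bank))
    cat(sprintf("  ICA bank: %d x (%d x %d); PCA bank: %d x (%d x %d)\n",
                x$ica_bank$L1, x$ica_bank$k1, x$ica_bank$k2,
                x$pca_bank$L2, x$pca_bank$k3, x$pca_bank$k4))
  cat(sprintf("  output weights: %d x %d; seed %d\n",
              nrow(x$Wnm), ncol(x$Wnm), x$seed))
  invisible(x)
}

# Internal: expanded matrix [Z | H] for new beats under a fitted model.
model_expand <- function(object, X) {
  X <- as.matrix(X)
  if (object$config$encoder == "cobls") {
    F_mat <- encode_features(X, object$ica_bank, object$pca_bank,
                             block_h = object$config$block_h,
                             block_w = object$config$block_w,
                             overlap = object$config$overlap,
                             normalize = object$config$hist_normalize,
                             center = object$config$center,
                             order = object$config$reshape_order)
  } else {
    F_mat <- X
  }
  Z <- if (is.null(object$scaler)) F_mat else apply_scaler(F_mat, object$scaler)
  H <- compute_enhancement(Z, object$W_h, object$beta_h,
                           object$config$activation)
  cbind(Z, H)
}

#' Predict classes (and scores) for new beats
#'
#' Each beat is encoded with the frozen filter banks and scaler, expanded
#' with the stored enhancement weights, and scored as `[f | H] Wnm`; the
#' predicted class is the argmax over `class_order`, ties broken toward the
#' lowest class index.
#'
#' @param object A fitted `cobls_model`.
#' @param X `N x 300` beat matrix or list of `heartbeat`s.
#' @param type `"class"` (default) for labels, `"score"` for the raw
#'   `N x L` score matrix.
#' @param ... Unused.
#' @return Character vector of labels, or the score matrix.
#' @export
predict.cobls_model <- function(object, X, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(object$Wnm)) stop("model is not fitted")
  if (is.list(X) && !is.matrix(X) && inherits(X[[1L]], "heartbeat"))
    X <- beat_stack(X)$X
  A <- model_expand(object, X)
  scores <- A %*% object$Wnm
  colnames(scores) <- object$class_order
  if (type == "score") return(scores)
  object$class_order[max.col(scores, ties.method = "first")]
}

#' Save / load a COBLS model archive
#'
#' The archive is a directory holding the serialised model object
#' (`model.rds`) next to a human-readable JSON sidecar (`config.json`) with
#' the configuration, seed and class order. Reloading reproduces
#' bit-identical predictions.
#'
#' @param model A `cobls_model`.
#' @param path Directory to create/overwrite.
#' @return `save_cobls` returns `path` invisibly; `load_cobls` returns the
#'   model.
#' @export
save_cobls <- function(model, path) {
  stopifnot(inherits(model, "cobls_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "cobls", format = 1L,
               config = unclass(model$config), seed = model$seed,
               class_order = model$class_order)
  jsonlite::write_json(meta, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(model, file.path(path, "model.rds"), version = 2L)
  invisible(path)
}

#' @rdname save_cobls
#' @export
load_cobls <- function(path) {
  f <- file.path(path, "model.rds")
  if (!file.exists(f)) stop("no model archive at ", path)
  readRDS(f)
}
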