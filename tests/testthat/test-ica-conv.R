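test_that("whitening satisfies V C V^T = I against a dense eigensolve", {
  set.seed(7)
  X <- matrix(stats::rnorm(49 * 500), 49, 500)
  X <- X - rowMeans(X)
  wh <- compute_whitening(X, 8)
  C <- X %*% t(X)
  expect_lt(max(abs(wh$V %*% C %*% t(wh$V) - diag(8))), 1e-6)
  # retained eigenvalues agree with eigen() on the dense covariance
  expect_equal(wh$eigenvalues[1:8], eigen(C, symmetric = TRUE)$values[1:8],
               tolerance = 1e-10)
})

test_that("whitening of isotropic patches is a scaled orthonormal projection", {
  # build patches whose covariance is exactly c * I via an orthogonal matrix
  set.seed(1)
  d <- 16; cval <- 4
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  X <- sqrt(cval) * Q            # X X^T = c I
  wh <- compute_whitening(X, 5)
  expect_lt(max(abs(wh$V %*% (X %*% t(X)) %*% t(wh$V) - diag(5))), 1e-8)
  expect_equal(apply(wh$V, 1, function(r) sum(r^2)), rep(1 / cval, 5),
               tolerance = 1e-8)
})

test_that("rank-deficient covariance engages the eigenvalue floor, no NaN", {
  set.seed(2)
  base <- matrix(stats::rnorm(49 * 3), 49, 3)
  X <- base %*% matrix(stats::rnorm(3 * 200), 3, 200)   # rank 3
  wh <- compute_whitening(X, 8)
  expect_true(all(is.finite(wh$V)))
  expect_equal(wh$C_rank, 3L)
  expect_error(compute_whitening(matrix(0, 49, 100), 8), "all-zero")
  expect_error(compute_whitening(X, 50), "exceeds")
})

test_that("FastICA recovers independent sources mixed by a known rotation", {
  set.seed(11)
  N <- 2000
  S <- matrix(stats::runif(2 * N, -1, 1), 2, N)   # independent, sub-Gaussian
  theta <- 0.6
  A <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  X <- A %*% S
  wh <- compute_whitening(X, 2)
  B <- fit_ica_unmixing(wh$V %*% X, 2, seed = 3)
  expect_lt(max(abs(B %*% t(B) - diag(2))), 1e-6)
  Y <- B %*% (wh$V %*% X)
  # each recovered component matches one source up to sign/permutation
  cors <- abs(stats::cor(t(Y), t(S)))
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
  expect_equal(sort(apply(cors, 1, which.max)), 1:2)
})

test_that("FastICA is deterministic per seed; seeds agree up to signed permutation", {
  set.seed(12)
  S <- matrix(stats::runif(2 * 1500, -1, 1), 2, 1500)
  A <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2, 2)
  X <- A %*% S
  wh <- compute_whitening(X, 2)
  Z <- wh$V %*% X
  B1 <- fit_ica_unmixing(Z, 2, seed = 5)
  B2 <- fit_ica_unmixing(Z, 2, seed = 5)
  expect_identical(unclass(B1)[, ], unclass(B2)[, ])
  B3 <- fit_ica_unmixing(Z, 2, seed = 99)
  P <- B3 %*% t(B1)       # should be near a signed permutation
  expect_equal(sort(apply(abs(P), 1, max)), c(1, 1), tolerance = 1e-2)
})

test_that("FastICA agrees with an independent reference on the rotation toy",  {
  skip_if_not(nzchar(Sys.which("python")))
  set.seed(21)
  N <- 1500
  S <- matrix(stats::runif(2 * N, -1, 1), 2, N)
  A <- matrix(c(cos(0.8), sin(0.8), -sin(0.8), cos(0.8)), 2, 2)
  X <- A %*% S
  wh <- compute_whitening(X, 2)
  Y <- fit_ica_unmixing(wh$V %*% X, 2, seed = 1) %*% (wh$V %*% X)
  f_in <- tempfile(fileext = ".csv"); f_out <- tempfile(fileext = ".csv")
  utils::write.table(t(X), f_in, sep = ",", row.names = FALSE, col.names = FALSE)
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.decomposition import FastICA\n",
    "X = np.loadtxt('%s', delimiter=',')\n",
    "ica = FastICA(n_components=2, whiten='unit-variance', random_state=0)\n",
    "np.savetxt('%s', ica.fit_transform(X), delimiter=',')\n"), f_in, f_out)
  res <- suppressWarnings(system2("python", "-", input = code,
                                  stdout = TRUE, stderr = TRUE))
  skip_if(!file.exists(f_out), "reference ICA unavailable")
  Yref <- t(as.matrix(utils::read.csv(f_out, header = FALSE)))
  cors <- abs(stats::cor(t(Y), t(Yref)))
  # same sources up to sign/permutation/scale
  expect_gt(max(cors[1, ]), 0.95)
  expect_gt(max(cors[2, ]), 0.95)
})

test_that("ICA kernels reshape rows of B V exactly", {
  set.seed(13)
  X <- matrix(stats::rnorm(49 * 400), 49, 400); X <- X - rowMeans(X)
  wh <- compute_whitening(X, 8)
  # Gaussian input has no ICA solution: the estimator warns and returns its
  # current (orthonormal) iterate, which is all the reshape check needs
  B <- suppressWarnings(fit_ica_unmixing(wh$V %*% X, 8, seed = 2))
  bank <- build_ica_filters(B, wh, 7, 7)
  expect_length(bank$kernels, 8L)
  expect_identical(dim(bank$kernels[[1L]]), c(7L, 7L))
  W <- B %*% wh$V
  for (l in 1:8)
    expect_identical(as.vector(bank$kernels[[l]]), W[l, ])
  # identity unmixing: kernels are the whitening rows reshaped
  bank_id <- build_ica_filters(diag(8), wh, 7, 7)
  expect_identical(as.vector(bank_id$kernels[[3L]]), wh$V[3L, ])
  expect_error(build_ica_filters(B, wh, 5, 5), "does not match")
})

test_that("same-padded filtering matches the brute-force oracle and is linear", {
  set.seed(14)
  M <- matrix(stats::rnorm(25), 5, 5)
  K <- matrix(stats::rnorm(9), 3, 3)
  got <- cobls:::conv2_same_one(M, K, center = FALSE)
  expect_equal(got, conv_oracle(M, K, center = FALSE), tolerance = 1e-12)
  got_c <- cobls:::conv2_same_one(M, K, center = TRUE)
  expect_equal(got_c, conv_oracle(M, K, center = TRUE), tolerance = 1e-12)

  # delta kernel is the identity without centring; zero kernel gives zero
  expect_equal(cobls:::conv2_same_one(M, delta_kernel(3, 3), center = FALSE), M)
  expect_true(all(cobls:::conv2_same_one(M, matrix(0, 3, 3), center = FALSE) == 0))

  # linearity on random inputs (centring disabled)
  X1 <- matrix(stats::rnorm(25), 5, 5); X2 <- matrix(stats::rnorm(25), 5, 5)
  lhs <- cobls:::conv2_same_one(2 * X1 - 3 * X2, K, center = FALSE)
  rhs <- 2 * cobls:::conv2_same_one(X1, K, center = FALSE) -
         3 * cobls:::conv2_same_one(X2, K, center = FALSE)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("ica_convolve produces shape-preserving primary feature blocks", {
  set.seed(15)
  beats <- matrix(stats::rnorm(10 * 300), 10, 300)
  cfg <- tiny_config()
  banks <- suppressWarnings(cobls:::learn_filter_banks(beats, cfg, seed = 1))
  M <- beat_to_matrix(beats[1L, ])
  pfb <- ica_convolve(M, banks$ica)
  expect_length(pfb$maps, cfg$L1)
  expect_identical(dim(pfb$maps[[1L]]), dim(M))
  # per-map equality with the brute-force oracle (centred placements)
  for (l in seq_len(cfg$L1))
    expect_equal(pfb$maps[[l]],
                 conv_oracle(M, banks$ica$kernels[[l]], center = TRUE),
                 tolerance = 1e-10)
})
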