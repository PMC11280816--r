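test_that("enhancement initialisation is seeded, scaled and shaped correctly", {
  e1 <- init_enhancement(10, m = 2, group_width = 5, seed = 42, s = 0.8)
  e2 <- init_enhancement(10, m = 2, group_width = 5, seed = 42, s = 0.8)
  expect_identical(e1, e2)
  expect_identical(dim(e1$W_h[[1L]]), c(10L, 5L))
  expect_length(e1$beta_h[[2L]], 5L)
  expect_true(all(abs(unlist(e1$W_h)) <= 0.8))

  e3 <- init_enhancement(10, m = 2, group_width = 5, seed = 43, s = 0.8)
  expect_false(identical(e1$W_h, e3$W_h))

  # one wide group; zero shrink kills the layer
  ew <- init_enhancement(7, m = 1, group_width = 9000, seed = 1)
  expect_identical(dim(ew$W_h[[1L]]), c(7L, 9000L))
  e0 <- init_enhancement(4, m = 1, group_width = 3, seed = 1, s = 0)
  H0 <- compute_enhancement(matrix(stats::rnorm(8), 2, 4), e0$W_h, e0$beta_h)
  expect_true(all(H0 == 0))        # tanh(0) = 0
})

test_that("enhancement activations match a hand computation and stay in (-1,1)", {
  Z <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  W <- matrix(c(0.1, -0.2, 0.3, 0.05, 0.15, -0.1), 3, 2)
  b <- c(0.2, -0.4)
  got <- compute_enhancement(Z, list(W), list(b))
  # hand-computed entries: (ZW)[1,1] = 1(0.1) + 3(-0.2) + 5(0.3) = 1.0;
  # (ZW)[2,1] = 2(0.1) + 4(-0.2) + 6(0.3) = 1.2;
  # (ZW)[1,2] = 1(0.05) + 3(0.15) + 5(-0.1) = 0.0;
  # (ZW)[2,2] = 2(0.05) + 4(0.15) + 6(-0.1) = 0.1; then + bias, then tanh
  expect_equal(got, tanh(matrix(c(1.0, 1.2, 0.0, 0.1), 2, 2) +
                         rep(b, each = 2)), tolerance = 1e-12)
  expect_equal(got[2, 2], tanh(0.1 - 0.4), tolerance = 1e-12)

  set.seed(1)
  Zb <- matrix(stats::rnorm(50), 10, 5)
  e <- init_enhancement(5, 1, 20, seed = 2)
  H <- compute_enhancement(Zb, e$W_h, e$beta_h)
  expect_true(all(H > -1 & H < 1))
  expect_error(compute_enhancement(Zb, list(matrix(0, 4, 2)), list(c(0, 0))),
               "does not match")
})

test_that("ridge solution matches the brute-force normal-equation oracle", {
  set.seed(20)
  A <- matrix(stats::rnorm(300), 30, 10)
  Y <- matrix(stats::rnorm(90), 30, 3)
  lam <- 1e-3
  W <- ridge_weights(A, Y, lam)
  W_oracle <- solve(lam * diag(10) + t(A) %*% A) %*% t(A) %*% Y
  expect_lt(max(abs(W - W_oracle)), 1e-8)

  # identity design, lambda = 0: W = Y
  expect_equal(ridge_weights(diag(5), matrix(1:10, 5, 2), 0),
               matrix(1:10, 5, 2), tolerance = 1e-12, ignore_attr = TRUE)

  # wide (dual-path) solve agrees with the primal normal equations
  Aw <- matrix(stats::rnorm(20 * 50), 20, 50)
  Ww <- ridge_weights(Aw, Y[1:20, , drop = FALSE], lam)
  W_oracle_w <- solve(lam * diag(50) + t(Aw) %*% Aw) %*% t(Aw) %*% Y[1:20, ]
  expect_lt(max(abs(Ww - W_oracle_w)), 1e-8)

  # rank-deficient A with lambda = 0 instructs a positive lambda
  Ad <- cbind(A[, 1], A[, 1], A[, 2])
  expect_error(ridge_weights(Ad, Y, 0), "positive")
})

test_that("ridge limits: shrinkage is monotone in lambda and lambda->0 hits the MP solution", {
  set.seed(21)
  A <- matrix(stats::rnorm(40 * 6), 40, 6)
  Y <- matrix(stats::rnorm(80), 40, 2)
  norms <- vapply(c(0.01, 0.1, 1, 10, 100, 1e4),
                  function(l) sqrt(sum(ridge_weights(A, Y, l)^2)), 0)
  expect_true(all(diff(norms) < 0))

  W_mp <- qr.coef(qr(A), Y)          # Moore-Penrose on full column rank
  errs <- vapply(c(1e-2, 1e-4, 1e-8),
                 function(l) max(abs(ridge_weights(A, Y, l) - W_mp)), 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("normal-equation residual and row-permutation equivariance hold", {
  set.seed(22)
  A <- matrix(stats::rnorm(60 * 8), 60, 8)
  Y <- matrix(stats::rnorm(120), 60, 2)
  lam <- 1e-4
  W <- ridge_weights(A, Y, lam)
  lhs <- (lam * diag(8) + t(A) %*% A) %*% W
  rhs <- t(A) %*% Y
  expect_lt(sqrt(sum((lhs - rhs)^2)) / sqrt(sum(rhs^2)), 1e-6)

  p <- sample(60)
  expect_lt(max(abs(ridge_weights(A[p, ], Y[p, ], lam) - W)), 1e-8)
})

test_that("fit separates the synthetic classes and predicts deterministically", {
  ds <- generate_dataset(c(N = 50, V = 50), snr_db = 24, seed = 30)
  cfg <- tiny_config()
  model <- cobls_fit(ds$X, ds$labels, cfg, seed = 7)
  expect_s3_class(model, "cobls_model")
  expect_identical(model$class_order, c("N", "V"))

  # resubstitution on well-separated classes is perfect
  expect_equal(mean(predict(model, ds$X) == as.character(ds$labels)), 1)

  # same seed -> identical held-out predictions
  hold <- generate_dataset(c(N = 20, V = 20), snr_db = 24, seed = 31)
  model2 <- cobls_fit(ds$X, ds$labels, cfg, seed = 7)
  expect_identical(predict(model, hold$X), predict(model2, hold$X))
  expect_identical(model$Wnm, model2$Wnm)

  # fitted-model normal-equation residual
  A <- cobls:::model_expand(model, ds$X)
  Y <- cobls:::one_hot(as.character(ds$labels), model$class_order)
  lhs <- cfg$lambda * model$Wnm + t(A) %*% (A %*% model$Wnm)
  rhs <- t(A) %*% Y
  expect_lt(sqrt(sum((lhs - rhs)^2)) / sqrt(sum(rhs^2)), 1e-6)

  expect_error(cobls_fit(ds$X, rep("N", nrow(ds$X)), cfg, seed = 1),
               "single class")
})

test_that("prediction handles degenerate beats and reports score shapes", {
  ds <- generate_dataset(c(N = 30, V = 30), snr_db = 24, seed = 32)
  model <- cobls_fit(ds$X, ds$labels, tiny_config(), seed = 3)
  sc <- predict(model, ds$X[1:5, ], type = "score")
  expect_identical(dim(sc), c(5L, 2L))
  expect_identical(colnames(sc), model$class_order)

  zero_scores <- predict(model, matrix(0, 1, 300), type = "score")
  expect_true(all(is.finite(zero_scores)))
  expect_true(predict(model, matrix(0, 1, 300)) %in% model$class_order)
})

test_that("model archive round-trips with bit-identical predictions", {
  ds <- generate_dataset(c(N = 25, V = 25), snr_db = 18, seed = 33)
  model <- cobls_fit(ds$X, ds$labels, tiny_config(), seed = 9)
  path <- withr::local_tempdir()
  save_cobls(model, file.path(path, "m1"))
  expect_true(file.exists(file.path(path, "m1", "config.json")))
  reloaded <- load_cobls(file.path(path, "m1"))
  expect_identical(predict(reloaded, ds$X), predict(model, ds$X))
  expect_identical(reloaded$Wnm, model$Wnm)
  expect_error(load_cobls(file.path(path, "nope")), "no model archive")
})
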