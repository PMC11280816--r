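test_that("confusion matrix counts pairs correctly", {
  yt <- c("a", "a", "b", "b", "c")
  cm <- confusion(yt, yt, c("a", "b", "c"))
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_identical(diag(unclass(cm)), c(a = 2L, b = 2L, c = 1L))

  yp <- c("a", "b", "b", "b", "c")        # one miss moves one count
  cm2 <- confusion(yt, yp, c("a", "b", "c"))
  expect_identical(sum(cm2), 5L)
  expect_identical(cm2["a", "b"], 1L)
  expect_identical(cm2["a", "a"], 1L)

  # brute-force pair-counting oracle on random labels
  set.seed(30)
  yt3 <- sample(letters[1:4], 200, replace = TRUE)
  yp3 <- sample(letters[1:4], 200, replace = TRUE)
  cm3 <- confusion(yt3, yp3, letters[1:4])
  for (i in letters[1:4]) for (j in letters[1:4])
    expect_identical(cm3[i, j], sum(yt3 == i & yp3 == j))
  expect_error(confusion(yt3, yp3, letters[1:3]), "not in class_order")
  expect_error(confusion(yt3, yp3[-1], letters[1:4]), "same length")
})

test_that("metric suite reproduces the published four-class worked example", {
  m <- classification_metrics(reference_confusion("DS1"))
  pc <- m$per_class
  r2 <- function(x) round_half_up(100 * x, 2)
  expect_equal(r2(m$OA), 99.11)
  expect_equal(r2(m$macro_PP), 96.95)
  expect_equal(r2(m$macro_SE), 89.71)
  expect_equal(r2(m$AF), 93.01)
  expect_equal(r2(pc$SE[pc$class == "N"]), 99.87)
  expect_equal(r2(pc$SE[pc$class == "S"]), 87.27)
  expect_equal(r2(pc$SE[pc$class == "F"]), 74.94)
  expect_equal(r2(pc$SPE[pc$class == "N"]), 93.87)
  expect_equal(r2(pc$F1[pc$class == "F"]), 83.07)
  expect_equal(r2(pc$Ac[pc$class == "N"]), 99.24)
  # accounting identities
  expect_equal(sum(pc$TP), 99559)
  expect_true(all(pc$TP + pc$TN + pc$FP + pc$FN == m$total))
  expect_identical(m$total, 100457L)
})

test_that("metric suite reproduces the published binary worked example", {
  m <- classification_metrics(reference_confusion("DS5"))
  expect_equal(round_half_up(100 * m$OA, 2), 99.01)
  pc <- m$per_class
  expect_equal(round_half_up(100 * pc$F1[pc$class == "Nb"], 2), 99.45)
  expect_equal(round_half_up(100 * pc$F1[pc$class == "Ab"], 2), 95.14)
  # the published average F1 (97.30) averages the two-decimal per-class
  # figures; the exact macro mean is 97.29(0), within one printed ulp
  expect_equal(round_half_up(mean(round_half_up(100 * pc$F1, 2)), 2), 97.30)
  expect_equal(100 * m$AF, 97.295, tolerance = 1e-4)
  expect_equal(round_half_up(100 * pc$SE[pc$class == "Ab"], 2), 92.56)
  expect_equal(round_half_up(100 * pc$PP[pc$class == "Nb"], 2), 99.13)
})

test_that("metrics handle perfection, permutation invariance and zero denominators", {
  cm <- confusion(rep(letters[1:3], 10), rep(letters[1:3], 10), letters[1:3])
  m <- classification_metrics(cm)
  expect_equal(m$OA, 1)
  expect_true(all(m$per_class[, c("Ac", "PP", "SE", "F1", "SPE")] == 1))

  # OA invariant under class reordering
  M <- matrix(c(5L, 1L, 2L, 8L), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  perm <- M[c(2, 1), c(2, 1)]
  expect_equal(classification_metrics(M)$OA,
               classification_metrics(perm)$OA)

  # a class never predicted and never present -> NaN rates, excluded macros
  M3 <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  M3[1, 1] <- 10L; M3[2, 2] <- 5L
  expect_warning(m3 <- classification_metrics(M3), "zero-denominator")
  expect_true(is.nan(m3$per_class$SE[3]))
  expect_equal(m3$macro_SE, 1)        # mean over the two defined classes
  expect_error(classification_metrics(matrix(0L, 2, 2)), "empty")
})

test_that("stratified folds partition the data with balanced class proportions", {
  labels <- c(rep("A", 50), rep("B", 50))
  f <- stratified_kfold(labels, k = 10, seed = 1)
  expect_identical(sort(unique(f)), 1:10)
  for (j in 1:10) {
    expect_identical(sum(f == j & labels == "A"), 5L)
    expect_identical(sum(f == j & labels == "B"), 5L)
  }
  # imbalanced labels: per-class fold sizes differ by at most one
  lab2 <- c(rep("A", 83), rep("B", 17))
  f2 <- stratified_kfold(lab2, k = 5, seed = 2)
  for (cl in c("A", "B")) {
    sizes <- table(f2[lab2 == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(stratified_kfold(labels, 10, seed = 3),
                   stratified_kfold(labels, 10, seed = 3))
  expect_error(stratified_kfold(c(rep("A", 20), rep("B", 3)), k = 10),
               "fewer than k")
})

test_that("cross-validation pools fold matrices and never leaks test labels", {
  ds <- generate_dataset(c(N = 30, V = 30), snr_db = 24, seed = 40)
  cfg <- tiny_config()
  labels <- as.character(ds$labels)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  cv <- cross_validate(ds$X, labels, cfg, seed = 1, folds = folds)
  expect_identical(sum(cv$confusion), 60L)
  expect_length(cv$per_fold, 5L)
  expect_equal(Reduce(`+`, lapply(cv$per_fold, function(p) unclass(p$confusion))),
               unclass(cv$confusion), ignore_attr = TRUE)

  # leakage check: poisoning fold-1 test labels must not change the model
  # evaluated on fold 1 (it is trained on the other folds only)
  poisoned <- labels
  i1 <- which(folds == 1L)
  poisoned[i1] <- ifelse(labels[i1] == "N", "V", "N")
  cv_p <- cross_validate(ds$X, poisoned, cfg, seed = 1, folds = folds)
  expect_identical(cv_p$per_fold[[1L]]$predicted, cv$per_fold[[1L]]$predicted)
})

test_that("pooled accuracy is stable under input shuffling on an easy task", {
  ds <- generate_dataset(c(N = 30, V = 30), snr_db = 24, seed = 41)
  cfg <- tiny_config()
  cv1 <- cross_validate(ds$X, ds$labels, cfg, k = 5, seed = 2)
  p <- sample(60)
  cv2 <- cross_validate(ds$X[p, ], as.character(ds$labels)[p], cfg, k = 5, seed = 2)
  expect_lt(abs(cv1$metrics$OA - cv2$metrics$OA), 0.005 + 1e-12)
})
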