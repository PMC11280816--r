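#' Confusion matrix (rows = actual, columns = predicted)
#'
#' @param y_true,y_pred Vectors of labels; every label must be in
#'   `class_order`.
#' @param class_order Character vector fixing the row/column order.
#' @return Integer `L x L` matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, class_order = sort(unique(c(y_true, y_pred)))) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad) > 0L)
    stop("labels not in class_order: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  out <- matrix(as.integer(cm), nrow = length(class_order),
                dimnames = list(actual = class_order, predicted = class_order))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Classification metric suite from a confusion matrix
#'
#' One-vs-rest accounting per class: `TP` is the diagonal cell, `FN` the
#' rest of the row, `FP` the rest of the column, `TN` the remainder. The
#' per-class rates are accuracy `Ac = (TP+TN)/total`, precision
#' `PP = TP/(TP+FP)`, sensitivity `SE = TP/(TP+FN)`,
#' `F1 = 2 PP SE/(PP+SE)` and specificity `SPE = TN/(TN+FP)`. Aggregates
#' are the macro means `AF` (mean F1), `ASPE` (mean specificity),
#' `macro_PP`, `macro_SE`, and the overall accuracy `OA = trace/total`.
#' Zero-denominator rates are reported as `NaN` with a warning and excluded
#' from the macro means.
#'
#' @param cm A `confusion_matrix` (or any square counts matrix with
#'   dimnames).
#' @return A `metrics_report`: list with `per_class` (data.frame), `AF`,
#'   `ASPE`, `OA`, `macro_PP`, `macro_SE`, `total`. All rates are
#'   proportions in `[0, 1]`; the print method shows percentages rounded
#'   half-up to 2 decimals.
#' @export
classification_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  L <- nrow(cm)
  classes <- rownames(cm) %||% as.character(seq_len(L))
  TP <- diag(cm)
  FN <- rowSums(cm) - TP
  FP <- colSums(cm) - TP
  TN <- total - TP - FN - FP
  safe_div <- function(num, den) ifelse(den == 0, NaN, num / den)
  Ac  <- (TP + TN) / total
  PP  <- safe_div(TP, TP + FP)
  SE  <- safe_div(TP, TP + FN)
  F1  <- safe_div(2 * PP * SE, PP + SE)
  SPE <- safe_div(TN, TN + FP)
  if (anyNA(c(PP, SE, F1, SPE)))
    warning("zero-denominator rate(s) reported as NaN and excluded from macro means")
  per_class <- data.frame(class = classes, TP = TP, TN = TN, FP = FP, FN = FN,
                          Ac = Ac, PP = PP, SE = SE, F1 = F1, SPE = SPE,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_class = per_class,
                 AF = mean(F1[!is.nan(F1)]),
                 ASPE = mean(SPE[!is.nan(SPE)]),
                 OA = sum(TP) / total,
                 macro_PP = mean(PP[!is.nan(PP)]),
                 macro_SE = mean(SE[!is.nan(SE)]),
                 total = total),
            class = "metrics_report")
}

#' Round half away from zero
#'
#' Deterministic half-up rounding used when formatting percentages for
#' comparison against published tables (base `round()` rounds half to
#' even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.metrics_report <- function(x, ...) {
  pc <- x$per_class
  fmt <- function(v) sprintf("%.2f", round_half_up(100 * v, 2L))
  tab <- data.frame(class = pc$class, TP = pc$TP, FN = pc$FN, FP = pc$FP,
                    `Ac%` = fmt(pc$Ac), `PP%` = fmt(pc$PP),
                    `SE%` = fmt(pc$SE), `F1%` = fmt(pc$F1),
                    `SPE%` = fmt(pc$SPE), check.names = FALSE)
  print(tab, row.names = FALSE)
  cat(sprintf("OA %s%%  macro-PP %s%%  macro-SE %s%%  AF %s%%  ASPE %s%%  (n = %d)\n",
              fmt(x$OA), fmt(x$macro_PP), fmt(x$macro_SE), fmt(x$AF),
              fmt(x$ASPE), x$total))
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Each class is shuffled with the seeded generator and dealt round-robin
#' over the k folds, so per-class fold sizes differ by at most one.
#'
#' @param labels Vector of class labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0L)
    stop(sprintf("class(es) with fewer than k = %d members: %s",
                 k, paste(small, collapse = ", ")))
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of a COBLS configuration
#'
#' For every fold the entire pipeline — filter banks, feature scaler and
#' ridge head — is re-learned on the k-1 training folds only (no leakage),
#' and the held-out fold is predicted. The pooled confusion matrix is the
#' sum of the per-fold test matrices and the reported metric suite is
#' computed from it (all-folds pooling).
#'
#' @param X Beats x 300 matrix.
#' @param labels Class labels.
#' @param config A [cobls_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment and per-fold fits (fold j uses
#'   `seed + j`).
#' @param folds Optional precomputed fold assignment (overrides
#'   `k`/`seed` fold generation).
#' @return A `cv_result`: list with `confusion` (pooled), `metrics`,
#'   `per_fold` (per-fold confusion matrices and predictions), `folds`.
#' @export
cross_validate <- function(X, labels, config = cobls_config(), k = 10L,
                           seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (is.null(folds)) folds <- stratified_kfold(labels, k = k, seed = seed)
  k <- max(folds)
  class_order <- sort(unique(labels))
  pooled <- matrix(0L, length(class_order), length(class_order),
                   dimnames = list(actual = class_order,
                                   predicted = class_order))
  per_fold <- vector("list", k)
  for (j in seq_len(k)) {
    tr <- folds != j
    te <- !tr
    model <- tryCatch(
      cobls_fit(X[tr, , drop = FALSE], labels[tr], config, seed = seed + j),
      error = function(e) stop(sprintf("fold %d: %s", j, conditionMessage(e)),
                               call. = FALSE))
    pred <- predict(model, X[te, , drop = FALSE])
    cmj <- confusion(labels[te], pred, class_order)
    pooled <- pooled + unclass(cmj)
    per_fold[[j]] <- list(fold = j, confusion = cmj,
                          index = which(te), predicted = pred)
  }
  pooled <- structure(pooled, class = c("confusion_matrix", "matrix"))
  structure(list(confusion = pooled,
                 metrics = classification_metrics(pooled),
                 per_fold = per_fold, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold pooled confusion matrix:\n", max(x$folds)))
  print(unclass(x$confusion))
  print(x$metrics)
  invisible(x)
}
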