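#' Published pooled confusion matrices for the MIT-BIH experiments
#'
#' Loads the reference all-folds confusion matrices shipped with the
#' package for the standard MIT-BIH task configurations: `"DS1"` (four
#' classes N/S/V/F), `"DS2"`-`"DS4"` (binary one-vs-normal) and `"DS5"`
#' (normal vs abnormal, Nb/Ab). They serve as desk-scale worked examples
#' for the metric suite ([classification_metrics()]) — e.g. the DS1 matrix
#' yields an overall accuracy of 99.11% — and as regression fixtures.
#'
#' @param name Dataset name, `"DS1"` ... `"DS5"`.
#' @return A `confusion_matrix` (rows = actual, columns = predicted).
#' @export
reference_confusion <- function(name = c("DS1", "DS2", "DS3", "DS4", "DS5")) {
  name <- match.arg(name)
  f <- system.file("extdata", paste0(tolower(name), "_confusion.csv"),
                   package = "cobls", mustWork = TRUE)
  df <- utils::read.csv(f, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = df[[1L]], predicted = colnames(df)[-1L])
  structure(m, class = c("confusion_matrix", "matrix"))
}
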