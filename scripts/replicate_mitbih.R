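#!/usr/bin/env Rscript
# OPTIONAL full-scale replication on the real MIT-BIH arrhythmia database.
# Requires the WFDB records (.hea/.dat/.atr) to be downloaded beforehand,
# e.g. from PhysioNet (https://physionet.org/content/mitdb/1.0.0/); nothing
# in the test suite or acceptance pipeline depends on this script.
#
# Usage:
#   Rscript scripts/replicate_mitbih.R --data <dir-with-records> \
#       [--dataset DS1] [--k 10] [--seed 1] [--out results/mitbih]
#
# Runs stratified 10-fold cross-validation of the full-size model
# (k = 7, L1 = L2 = 8, 9000 enhancement nodes) on the requested dataset
# configuration and writes the pooled confusion matrix and metric table.
# With ~100k beats this needs hours of CPU time and tens of GB of memory;
# use --filter-beats / --enh-width to scale down.

suppressPackageStartupMessages(library(cobls))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(data = NULL, dataset = "DS1", k = 10L, seed = 1L,
            out = "results/mitbih", filter_beats = 2000L, enh_width = 9000L)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  key <- gsub("-", "_", key)
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- if (is.numeric(opt[[key]]) || is.integer(opt[[key]]))
    as.integer(args[i + 1L]) else args[i + 1L]
  i <- i + 2L
}
if (is.null(opt$data)) stop("--data <dir> is required (downloaded WFDB records)")

# conventional exclusion of the paced records; 46 usable recordings remain
excluded <- c("102", "104")
headers <- list.files(opt$data, pattern = "\\.hea$", full.names = TRUE)
names <- sub("\\.hea$", "", basename(headers))
keep <- !(names %in% excluded)
message(sum(keep), " records (excluded: ",
        paste(names[!keep], collapse = ", "), ")")

records <- lapply(file.path(opt$data, names[keep]), read_record)
ds <- build_dataset(records, dataset_spec(opt$dataset))
message("achieved class counts:")
print(ds$counts)

cfg <- cobls_config(enh_width = opt$enh_width,
                    filter_beats = opt$filter_beats)
cv <- cross_validate(ds$X, ds$labels, cfg, k = opt$k, seed = opt$seed)
print(cv)

dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
utils::write.csv(as.data.frame(unclass(cv$confusion)),
                 file.path(opt$out, paste0(opt$dataset, "_confusion.csv")))
utils::write.csv(cv$metrics$per_class,
                 file.path(opt$out, paste0(opt$dataset, "_metrics.csv")),
                 row.names = FALSE)
message("written to ", opt$out)
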