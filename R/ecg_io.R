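# Minimal WFDB (PhysioNet) record I/O: text .hea headers, .dat signal files
# in formats 16 (16-bit little-endian) and 212 (packed 12-bit pairs), and
# MIT-format .atr annotation files. Covers what MIT-BIH records need; it is
# not a general WFDB implementation (no multi-segment records, no skew or
# byte offsets).

# MIT annotation code <-> symbol table (beat and common non-beat codes).
wfdb_ann_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

#' Map MIT-BIH annotation symbols to AAMI superclasses
#'
#' Implements the standard five-superclass grouping: N (normal, left/right
#' bundle branch block, atrial and nodal escape), S (atrial premature,
#' aberrated atrial premature, nodal premature, supraventricular premature),
#' V (premature ventricular contraction, ventricular escape), F (fusion of
#' ventricular and normal), Q (paced, fusion of paced and normal,
#' unclassifiable). Non-beat annotations and unknown symbols map to
#' `"drop"`. Q beats are retained by the mapper but excluded from
#' experiments downstream.
#'
#' @param symbols Character vector of annotation symbols.
#' @return Character vector over `{"N","S","V","F","Q","drop"}`.
#' @export
map_aami <- function(symbols) {
  map <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
           A = "S", a = "S", J = "S", S = "S",
           V = "V", E = "V",
           F = "F",
           "/" = "Q", f = "Q", Q = "Q")
  out <- map[as.character(symbols)]
  out[is.na(out)] <- "drop"
  unname(out)
}

parse_gain_spec <- function(txt) {
  # forms: "200", "200(0)", "200(0)/mV"
  units <- NA_character_
  baseline <- NA_real_
  if (grepl("/", txt, fixed = TRUE)) {
    parts <- strsplit(txt, "/", fixed = TRUE)[[1L]]
    units <- parts[2L]
    txt <- parts[1L]
  }
  if (grepl("(", txt, fixed = TRUE)) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", txt))
    txt <- sub("\\(.*", "", txt)
  }
  list(gain = as.numeric(txt), baseline = baseline, units = units)
}

#' Read a WFDB record with its annotations
#'
#' Parses the `.hea` header, reads the `.dat` signal file (formats 16 and
#' 212), converts ADC counts to physical units using the per-signal
#' gain/baseline, and reads the `.atr` annotation file when present.
#'
#' @param path Record path without extension (e.g. `"data/100"`).
#' @param annotator Annotation file extension (default `"atr"`).
#' @return An `annotated_record`: list with `signal` (samples x leads
#'   matrix, physical units), `fs`, `lead_names`, `r_peaks` (1-based sample
#'   indices), `symbols`, `record`.
#' @export
read_record <- function(path, annotator = "atr") {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("missing header file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record <- sub("/.*", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (is.na(nsig) || nsig < 1L) stop("malformed header: ", hea)
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1L + i]), "\\s+")[[1L]]
    g <- parse_gain_spec(if (length(f) >= 3L) f[3L] else "200")
    adczero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    sig[[i]] <- list(
      file = f[1L],
      format = as.integer(sub("[x:+].*", "", f[2L])),
      gain = if (is.na(g$gain) || g$gain == 0) 200 else g$gain,
      baseline = if (is.na(g$baseline)) adczero else g$baseline,
      units = g$units,
      desc = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
             else paste0("sig", i))
  }
  dat <- file.path(dirname(path), sig[[1L]]$file)
  if (!file.exists(dat)) stop("missing signal file: ", dat)
  fmt <- sig[[1L]]$format
  raw_n <- file.info(dat)$size
  if (fmt == 16L) {
    samples <- readBin(dat, "integer", n = raw_n %/% 2L, size = 2L,
                       signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    bytes <- as.integer(readBin(dat, "raw", n = raw_n))
    ntrip <- length(bytes) %/% 3L
    b1 <- bytes[3L * seq_len(ntrip) - 2L]
    b2 <- bytes[3L * seq_len(ntrip) - 1L]
    b3 <- bytes[3L * seq_len(ntrip)]
    s1 <- bitwAnd(b2, 15L) * 256L + b1
    s2 <- bitwAnd(b2, 240L) * 16L + b3
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    samples <- as.vector(rbind(s1, s2))
  } else stop("unsupported WFDB signal format: ", fmt)
  total <- (length(samples) %/% nsig) * nsig
  M <- matrix(samples[seq_len(total)], nrow = nsig)
  if (!is.na(nsamp) && ncol(M) > nsamp) M <- M[, seq_len(nsamp), drop = FALSE]
  phys <- t((M - vapply(sig, `[[`, numeric(1L), "baseline")) /
            vapply(sig, `[[`, numeric(1L), "gain"))
  lead_names <- vapply(sig, `[[`, character(1L), "desc")
  colnames(phys) <- lead_names
  ann_file <- paste0(path, ".", annotator)
  ann <- if (file.exists(ann_file)) read_annotations(ann_file)
         else data.frame(sample = integer(0), symbol = character(0))
  structure(list(signal = phys, fs = fs, lead_names = lead_names,
                 r_peaks = ann$sample, symbols = ann$symbol,
                 record = record),
            class = "annotated_record")
}

#' @export
print.annotated_record <- function(x, ...) {
  cat(sprintf("<annotated_record> %s: %d samples x %d lead(s) [%s] @ %g Hz, %d annotations\n",
              x$record, nrow(x$signal), ncol(x$signal),
              paste(x$lead_names, collapse = ", "), x$fs, length(x$r_peaks)))
  invisible(x)
}

#' Select one lead from an annotated record
#'
#' @param record An `annotated_record`.
#' @param lead Lead name (e.g. `"MLII"`).
#' @return Numeric vector of that lead's samples.
#' @export
get_lead <- function(record, lead = "MLII") {
  i <- match(lead, record$lead_names)
  if (is.na(i))
    stop(sprintf("lead '%s' not found; available leads: %s",
                 lead, paste(record$lead_names, collapse = ", ")))
  record$signal[, i]
}

# MIT annotation file reader: stream of 16-bit little-endian words,
# code = word >> 10, time delta = word & 0x3FF. Handles SKIP (59, 4-byte
# PDP-11 long interval), AUX (63, padded string) and the NUM/SUB/CHN
# modifiers (60-62, ignored).
read_annotations <- function(file) {
  raw_b <- readBin(file, "raw", n = file.info(file)$size)
  b <- as.integer(raw_b)
  n <- length(b) %/% 2L
  samples <- integer(0); symbols <- character(0)
  t_cur <- 0L; i <- 1L
  while (i <= n) {
    lo <- b[2L * i - 1L]; hi <- b[2L * i]
    word <- hi * 256L + lo
    code <- word %/% 1024L
    delta <- word %% 1024L
    i <- i + 1L
    if (code == 0L && delta == 0L) break
    if (code == 59L) {            # SKIP: next two words hold a long interval
      if (delta == 0L) {
        hi_w <- b[2L * i] * 256L + b[2L * i - 1L]
        lo_w <- b[2L * (i + 1L)] * 256L + b[2L * (i + 1L) - 1L]
        t_cur <- t_cur + hi_w * 65536L + lo_w
        i <- i + 2L
      }
    } else if (code == 63L) {     # AUX: delta = byte count, padded to even
      i <- i + (delta + delta %% 2L) %/% 2L
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN modifiers: no time advance
    } else {
      t_cur <- t_cur + delta
      sym <- wfdb_ann_codes[as.character(code)]
      samples <- c(samples, t_cur)
      symbols <- c(symbols, if (is.na(sym)) "?" else sym)
    }
  }
  # WFDB times are 0-based sample counts; convert to 1-based indices
  data.frame(sample = samples + 1L, symbol = symbols,
             stringsAsFactors = FALSE)
}

#' Write a WFDB record (header, signal, annotations)
#'
#' Counterpart of [read_record()] for interoperability testing and dataset
#' export. Signals are quantised to ADC counts with the given gain
#' (round-trip error at most `0.5 / gain`).
#'
#' @param signal Numeric vector or samples x leads matrix (physical units).
#' @param dir Output directory.
#' @param record Record name.
#' @param fs Sampling rate in Hz.
#' @param lead_names Lead names (default `"MLII"`, `"V1"`, ...).
#' @param ann Optional data.frame with `sample` (1-based) and `symbol`.
#' @param gain ADC gain (counts per physical unit, default 200).
#' @param format WFDB signal format: 16 (default) or 212.
#' @return The record path (without extension), invisibly.
#' @export
write_record <- function(signal, dir, record, fs = 360,
                         lead_names = NULL, ann = NULL,
                         gain = 200, format = 16L) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  nsig <- ncol(signal); nsamp <- nrow(signal)
  if (is.null(lead_names))
    lead_names <- c("MLII", "V1", paste0("sig", seq_len(max(0L, nsig - 2L))))[seq_len(nsig)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adc <- round(signal * gain)
  adc <- pmin(pmax(adc, if (format == 212L) -2048 else -32768),
              if (format == 212L) 2047 else 32767)
  dat_name <- paste0(record, ".dat")
  inter <- as.vector(t(adc))          # interleave leads sample by sample
  if (format == 16L) {
    writeBin(as.integer(inter), file.path(dir, dat_name), size = 2L,
             endian = "little")
  } else if (format == 212L) {
    if (length(inter) %% 2L == 1L) inter <- c(inter, 0)
    v <- as.integer(inter) %% 4096L   # 12-bit two's complement
    s1 <- v[seq(1L, length(v), 2L)]
    s2 <- v[seq(2L, length(v), 2L)]
    b1 <- s1 %% 256L
    b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
    b3 <- s2 %% 256L
    writeBin(as.raw(as.vector(rbind(b1, b2, b3))), file.path(dir, dat_name))
  } else stop("unsupported WFDB signal format: ", format)
  hea <- c(sprintf("%s %d %g %d", record, nsig, fs, nsamp),
           vapply(seq_len(nsig), function(i)
             sprintf("%s %d %g(0)/mV 12 0 0 0 0 %s",
                     dat_name, format, gain, lead_names[i]),
             character(1L)))
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  if (!is.null(ann)) write_annotations(ann, file.path(dir, paste0(record, ".atr")))
  invisible(file.path(dir, record))
}

write_annotations <- function(ann, file) {
  stopifnot(all(c("sample", "symbol") %in% names(ann)))
  ann <- ann[order(ann$sample), , drop = FALSE]
  code_of <- stats::setNames(as.integer(names(wfdb_ann_codes)), wfdb_ann_codes)
  out <- integer(0)
  t_prev <- 0L
  for (i in seq_len(nrow(ann))) {
    t0 <- ann$sample[i] - 1L          # back to 0-based WFDB time
    delta <- t0 - t_prev
    if (delta > 1023L || delta < 0L) {
      out <- c(out, 59L * 1024L,
               (delta %/% 65536L) %% 65536L, delta %% 65536L)
      delta <- 0L
    }
    code <- code_of[ann$symbol[i]]
    if (is.na(code)) code <- 13L      # unclassifiable
    out <- c(out, code * 1024L + delta)
    t_prev <- t0
  }
  out <- c(out, 0L)                   # EOF word
  lo <- out %% 256L
  hi <- out %/% 256L
  writeBin(as.raw(as.vector(rbind(lo, hi))), file)
}

#' Dataset configuration for the standard experiments
#'
#' DS1 is the four-class task (N, S, V, F); DS2-DS4 are the one-vs-normal
#' binary tasks (N/S, N/V, N/F); DS5 and DS6 are the normal-vs-abnormal
#' binary tasks where Nb = N and Ab = S, V and F relabelled together (DS6
#' is the noise-stress variant).
#'
#' @param name One of `"DS1" ... "DS6"`.
#' @return A `dataset_spec`: list with `name`, `classes` (retained AAMI
#'   classes) and `relabel` (named map applied after filtering, or `NULL`).
#' @export
dataset_spec <- function(name = c("DS1", "DS2", "DS3", "DS4", "DS5", "DS6")) {
  name <- match.arg(name)
  spec <- switch(name,
    DS1 = list(classes = c("N", "S", "V", "F"), relabel = NULL),
    DS2 = list(classes = c("N", "S"), relabel = NULL),
    DS3 = list(classes = c("N", "V"), relabel = NULL),
    DS4 = list(classes = c("N", "F"), relabel = NULL),
    DS5 = ,
    DS6 = list(classes = c("N", "S", "V", "F"),
               relabel = c(N = "Nb", S = "Ab", V = "Ab", F = "Ab")))
  structure(c(list(name = name), spec), class = "dataset_spec")
}

#' Assemble a labelled beat collection from annotated records
#'
#' Segments every record (see [segment_beats()]), keeps the spec's classes,
#' applies the spec's relabelling (Nb/Ab for DS5/DS6) and reports achieved
#' per-class counts.
#'
#' @param records List of `annotated_record` objects.
#' @param spec A [dataset_spec()].
#' @param lead Lead to use (default `"MLII"`).
#' @return List with `X` (beats x 300 matrix), `labels` (factor) and
#'   `counts` (data.frame of achieved per-class counts).
#' @export
build_dataset <- function(records, spec, lead = "MLII") {
  stopifnot(inherits(spec, "dataset_spec"))
  if (inherits(records, "annotated_record")) records <- list(records)
  all_beats <- list()
  for (rec in records) {
    sig <- get_lead(rec, lead)
    all_beats <- c(all_beats,
                   segment_beats(sig, rec$r_peaks, rec$symbols))
  }
  if (length(all_beats) == 0L) stop("no beats segmented from the given records")
  st <- beat_stack(all_beats)
  keep <- as.character(st$labels) %in% spec$classes
  if (!any(keep)) stop("no beats match the classes of ", spec$name)
  X <- st$X[keep, , drop = FALSE]
  labels <- as.character(st$labels)[keep]
  if (!is.null(spec$relabel)) labels <- unname(spec$relabel[labels])
  labels <- factor(labels)
  counts <- as.data.frame(table(class = labels), stringsAsFactors = FALSE)
  names(counts) <- c("class", "count")
  list(X = X, labels = labels, counts = counts)
}
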