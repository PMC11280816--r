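# Synthetic single-beat ECG generator.
#
# Each beat is a sum of Gaussian bumps (one per ECG wave) on a 300-sample
# window at 360 Hz, R-peak aligned to sample 150 (1-based) to match the
# segmentation convention (149 samples before the peak, 150 after). The
# class morphologies follow the usual clinical caricatures: S beats have an
# early, attenuated P wave and a narrowed QRS; V beats have a wide,
# high-amplitude QRS with no P wave and an inverted T; F beats are the
# pointwise average of the N and V templates (fusion of ventricular and
# normal activation).

beat_wave_table <- list(
  N = data.frame(wave   = c("P", "Q", "R", "S", "T"),
                 center = c(92, 142, 150, 158, 218),
                 width  = c(9, 3.5, 4.5, 3.5, 16),
                 amp    = c(0.17, -0.12, 1.00, -0.22, 0.32)),
  S = data.frame(wave   = c("P", "Q", "R", "S", "T"),
                 center = c(70, 143, 150, 157, 215),
                 width  = c(6, 3.0, 3.2, 3.0, 14),
                 amp    = c(0.06, -0.10, 0.95, -0.18, 0.28)),
  V = data.frame(wave   = c("Q", "R", "S", "T"),
                 center = c(138, 150, 166, 225),
                 width  = c(7, 11, 9, 20),
                 amp    = c(-0.28, 1.25, -0.50, -0.35))
)

gaussian_bumps <- function(params, n = 300L, shift = 0) {
  t <- seq_len(n)
  v <- numeric(n)
  for (i in seq_len(nrow(params)))
    v <- v + params$amp[i] *
      exp(-(t - (params$center[i] + shift))^2 / (2 * params$width[i]^2))
  v
}

#' Noise-free beat template for an AAMI class
#'
#' Deterministic sum-of-Gaussians morphology, 300 samples, R-peak at sample
#' 150 (1-based). The F template is exactly the pointwise mean of the N and
#' V templates. The wave parameter table is exported as
#' `beat_template_params()`.
#'
#' @param class One of `"N"`, `"S"`, `"V"`, `"F"`.
#' @param n Beat length in samples (default 300).
#' @param shift Latency shift in samples applied to all wave centres.
#' @return Numeric vector of length `n` (arbitrary units, R amplitude ~1).
#' @export
make_template <- function(class, n = 300L, shift = 0) {
  if (!is.character(class) || length(class) != 1L ||
      !class %in% c("N", "S", "V", "F"))
    stop("unknown beat class: ", paste(class, collapse = ","))
  if (class == "F")
    return((gaussian_bumps(beat_wave_table$N, n, shift) +
            gaussian_bumps(beat_wave_table$V, n, shift)) / 2)
  gaussian_bumps(beat_wave_table[[class]], n, shift)
}

#' @rdname make_template
#' @export
beat_template_params <- function(class) {
  if (class == "F") stop("F is derived: mean of the N and V tables")
  beat_wave_table[[class]]
}

#' Generate a labelled synthetic beat dataset
#'
#' Each beat is its class template perturbed by seeded random amplitude
#' scaling (+/- 10%), an integer latency shift (+/- 3 samples, waves
#' re-windowed), and a smooth baseline-wander sinusoid; Gaussian white noise
#' is then injected at the target SNR (exact post-hoc scaling, see
#' [add_noise()]). Deterministic given `seed`.
#'
#' @param n_per_class Named integer vector, e.g. `c(N = 200, V = 200)`.
#' @param snr_db Target signal-to-noise ratio in dB (`Inf` = clean).
#' @param seed Integer seed for all randomness.
#' @param amp_jitter Half-range of the uniform amplitude scaling (0.10).
#' @param shift_jitter Maximum absolute latency shift in samples (3).
#' @param baseline_amp Maximum baseline-wander amplitude (0.05 a.u.).
#' @return An `ecg_dataset`: list with `X` (beats x 300 noisy matrix),
#'   `clean` (pre-noise matrix), `labels` (factor), `snr_db`, `seed`.
#' @export
generate_dataset <- function(n_per_class = c(N = 200L, V = 200L),
                             snr_db = Inf, seed = 1L,
                             amp_jitter = 0.10, shift_jitter = 3L,
                             baseline_amp = 0.05) {
  stopifnot(!is.null(names(n_per_class)), all(n_per_class >= 0))
  classes <- rep(names(n_per_class), times = n_per_class)
  n_beats <- length(classes)
  n <- 300L
  withr::with_seed(seed, {
    clean <- matrix(0, n_beats, n)
    for (i in seq_len(n_beats)) {
      scale <- 1 + stats::runif(1, -amp_jitter, amp_jitter)
      shift <- if (shift_jitter > 0) sample(-shift_jitter:shift_jitter, 1L) else 0L
      amp_b <- baseline_amp * stats::runif(1, 0.5, 1)
      freq  <- stats::runif(1, 0.3, 1.2)
      phase <- stats::runif(1, 0, 2 * pi)
      wander <- amp_b * sin(2 * pi * freq * seq_len(n) / n + phase)
      clean[i, ] <- scale * make_template(classes[i], n, shift) + wander
    }
    X <- clean
    if (is.finite(snr_db))
      for (i in seq_len(n_beats))
        X[i, ] <- add_noise(clean[i, ], snr_db)
    structure(list(X = X, clean = clean,
                   labels = factor(classes, levels = names(n_per_class)),
                   snr_db = snr_db, seed = as.integer(seed)),
              class = "ecg_dataset")
  })
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d beats x %d samples, SNR %s dB, seed %d\n",
              nrow(x$X), ncol(x$X),
              ifelse(is.finite(x$snr_db), format(x$snr_db), "Inf"), x$seed))
  print(table(x$labels))
  invisible(x)
}

#' Add Gaussian white noise at an exact target SNR
#'
#' The noise vector is sampled, then rescaled so that the realised
#' `10 log10(sum(s^2) / sum(n^2))` equals `snr_db` exactly (post-hoc
#' scaling, not expected-power scaling), making [measure_snr()] an exact
#' inverse.
#'
#' @param signal Numeric vector; must be nonzero for a finite target.
#' @param snr_db Target SNR in dB; `Inf` returns the signal unchanged.
#' @param seed Optional integer seed; `NULL` (default) draws from the
#'   current RNG stream.
#' @return Noisy signal of the same length.
#' @export
add_noise <- function(signal, snr_db, seed = NULL) {
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  ps <- sum(signal^2)
  if (ps == 0) stop("zero signal: finite target SNR is undefined")
  draw <- function() stats::rnorm(length(signal))
  noise <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  alpha <- sqrt(ps / (sum(noise^2) * 10^(snr_db / 10)))
  signal + alpha * noise
}

#' Realised signal-to-noise ratio in dB
#'
#' `10 log10(sum(clean^2) / sum((noisy - clean)^2))`; returns `Inf` when the
#' two signals are identical.
#'
#' @param clean,noisy Numeric vectors of equal length.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  stopifnot(length(clean) == length(noisy))
  if (sum(clean^2) == 0) stop("zero clean signal: SNR is undefined")
  pn <- sum((noisy - clean)^2)
  if (pn == 0) return(Inf)
  10 * log10(sum(clean^2) / pn)
}
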