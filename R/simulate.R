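# Seeded synthetic EEG generator in the STEW plain-text dialect.
#
# Each channel is a sum of five band-limited sinusoids (one per canonical
# EEG band, random centre frequency and phase) plus pink (1/f) and white
# noise. The class contrast is the standard stress signature: alpha
# suppression with beta elevation under load. Channels are independent --
# no volume conduction or artifact model is attempted.

# Emulated electrode column order (Emotiv EPOC montage). A documented
# convention of this dialect, not a claim about the upstream corpus.

#' Electrode column order of the emulated dialect
#' @export
STEW_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                   "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

# Oscillator centre-frequency ranges (Hz). Alpha/beta sit on the dyadic
# 8-16 / 16-32 Hz edges so that the wavelet D3/D2 bands capture them;
# gamma is kept well under the 64 Hz Nyquist limit.
.band_freq_ranges <- list(
  delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 16),
  beta = c(16, 32), gamma = c(32, 45))

.default_band_amplitudes <- function() {
  list(
    relax  = c(delta = 0.5, theta = 0.5, alpha = 2.0, beta = 0.5, gamma = 0.5),
    stress = c(delta = 0.5, theta = 0.5, alpha = 0.8, beta = 1.8, gamma = 0.5))
}

#' Synthetic EEG simulation configuration
#'
#' Defaults mirror the geometry of the emulated workload corpus: 48
#' subjects, two conditions per subject, 14 channels, 150 s at 128 Hz
#' (19,200 samples per channel per recording; 921,600 per channel summed
#' over the 48 subjects of one condition).
#'
#' @param n_subjects Number of subjects (each yields one "lo" rest and one
#'   "hi" task recording).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of electrode channels (names are recycled or
#'   truncated from the standard 14-electrode montage).
#' @param band_amplitudes Named list with elements `relax` and `stress`,
#'   each a named numeric vector of per-band oscillator amplitudes
#'   (delta, theta, alpha, beta, gamma); all non-negative.
#' @param pink_noise_scale Standard deviation of the 1/f noise component.
#' @param white_noise_scale Standard deviation of the white noise component.
#' @param seed Base integer seed; all randomness in the generator derives
#'   from it deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 48L, duration = 150, fs = 128,
                       n_channels = 14L,
                       band_amplitudes = .default_band_amplitudes(),
                       pink_noise_scale = 1.0, white_noise_scale = 0.5,
                       seed = 1L) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  n_subjects <- as.integer(n_subjects)
  n_channels <- as.integer(n_channels)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (n_channels < 1L) stop("n_channels must be >= 1", call. = FALSE)
  if (!all(c("relax", "stress") %in% names(band_amplitudes)))
    stop("band_amplitudes must contain 'relax' and 'stress'", call. = FALSE)
  for (cond in c("relax", "stress")) {
    amps <- band_amplitudes[[cond]]
    if (!all(names(.band_freq_ranges) %in% names(amps)))
      stop("band_amplitudes$", cond, " must name all of: ",
           paste(names(.band_freq_ranges), collapse = ", "), call. = FALSE)
    if (any(amps < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (pink_noise_scale < 0 || white_noise_scale < 0)
    stop("noise scales must be non-negative", call. = FALSE)
  structure(
    list(n_subjects = n_subjects, duration = duration, fs = fs,
         n_channels = n_channels, band_amplitudes = band_amplitudes,
         pink_noise_scale = pink_noise_scale,
         white_noise_scale = white_noise_scale, seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic per-recording sub-seed, kept inside 32-bit integer range
.recording_seed <- function(seed, subject, condition) {
  h <- (as.double(seed) * 100003 + as.double(subject) * 131 +
          ifelse(condition == "stress", 7919, 0)) %% 2147483647
  as.integer(h)
}

.normalize_condition <- function(condition) {
  switch(condition,
         relax = "relax", lo = "relax",
         stress = "stress", hi = "stress",
         stop("unknown condition '", condition,
              "'; expected relax/lo or stress/hi", call. = FALSE))
}

# pink (1/f power) noise by spectral shaping of white noise, unit variance
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                 # avoid the DC bin
  f <- pmin(f, n - f + 1)                   # fold to two-sided frequencies
  shaped <- spec / sqrt(f)
  shaped[1] <- 0
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate one synthetic recording
#'
#' Deterministic given `(config$seed, subject, condition)`. Each channel is
#' an independent draw of the band-oscillator + pink + white noise model;
#' the workload rating is drawn uniformly from 1-3 ("relax") or 7-9
#' ("stress"), matching the low/high burden bands of the rating scale.
#'
#' @param config A [sim_config()].
#' @param subject Subject index in `1:n_subjects`.
#' @param condition `"relax"`/`"lo"` or `"stress"`/`"hi"`.
#' @return An `eeg_recording` (see [new_recording()]).
#' @export
generate_recording <- function(config, subject, condition) {
  stopifnot(inherits(config, "sim_config"))
  condition <- .normalize_condition(condition)
  subject <- as.integer(subject)
  if (is.na(subject) || subject < 1L || subject > config$n_subjects)
    stop("subject must lie in 1..", config$n_subjects, call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(.recording_seed(config$seed, subject, condition))

  n <- round(config$duration * config$fs)
  tt <- (seq_len(n) - 1) / config$fs
  amps <- config$band_amplitudes[[condition]]

  rating <- if (condition == "relax") sample(1:3, 1L) else sample(7:9, 1L)

  data <- matrix(0, nrow = config$n_channels, ncol = n)
  for (ch in seq_len(config$n_channels)) {
    sig <- numeric(n)
    for (band in names(.band_freq_ranges)) {
      rng <- .band_freq_ranges[[band]]
      f0 <- stats::runif(1, rng[1], rng[2])
      phase <- stats::runif(1, 0, 2 * pi)
      sig <- sig + amps[[band]] * sin(2 * pi * f0 * tt + phase)
    }
    if (config$pink_noise_scale > 0)
      sig <- sig + config$pink_noise_scale * .pink_noise(n)
    if (config$white_noise_scale > 0)
      sig <- sig + config$white_noise_scale * stats::rnorm(n)
    data[ch, ] <- sig
  }

  ch_names <- rep_len(STEW_CHANNELS, config$n_channels)
  new_recording(data, fs = config$fs, channel_names = ch_names,
                subject_id = subject,
                condition = if (condition == "relax") "lo" else "hi",
                rating = rating)
}

#' Write a recording in the STEW dialect
#'
#' Whitespace-delimited plain text, no header, one row per time sample and
#' one column per channel, fixed 6-decimal formatting (round-trip accurate
#' to 1e-6).
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  cols <- lapply(seq_len(nrow(recording$data)),
                 function(i) sprintf("%.6f", recording$data[i, ]))
  lines <- do.call(paste, c(cols, list(sep = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a full synthetic dataset on disk
#'
#' Writes `n_subjects x 2` recordings named `sub{NN}_{lo|hi}.txt` plus a
#' `ratings.txt` file with lines `subject,condition,rating`. Byte-identical
#' output for identical configs.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a manifest data frame with columns `path`, `subject`,
#'   `condition`, `rating`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir, call. = FALSE)

  rows <- list()
  ratings_lines <- character(0)
  for (subject in seq_len(config$n_subjects)) {
    for (cond in c("lo", "hi")) {
      rec <- generate_recording(config, subject, cond)
      fname <- sprintf("sub%02d_%s.txt", subject, cond)
      path <- file.path(out_dir, fname)
      write_recording(rec, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, subject = subject, condition = cond,
        rating = rec$rating, stringsAsFactors = FALSE)
      ratings_lines <- c(ratings_lines,
                         sprintf("%d,%s,%d", subject, cond, rec$rating))
    }
  }
  writeLines(ratings_lines, file.path(out_dir, "ratings.txt"))
  invisible(do.call(rbind, rows))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_subjects, " subjects x 2 conditions, ",
      x$n_channels, " channels, ", x$duration, " s @ ", x$fs, " Hz, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}
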