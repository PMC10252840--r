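# Shared fixtures: small simulation configs, an independent periodogram
# band-energy oracle, and toy separable window sets.

tiny_sim <- function(seed = 1, n_subjects = 2L, duration = 10, ...) {
  sim_config(n_subjects = n_subjects, duration = duration, seed = seed, ...)
}

# independent spectral oracle: band energy from the raw periodogram,
# deliberately not using any wavelet code
periodogram_band_energy <- function(x, fs, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1)
  sum(p[half][freq[half] >= low & freq[half] < high])
}
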