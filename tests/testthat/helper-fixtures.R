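# Shared small configurations and fixtures, generated in code.

# A fast subject configuration: analysis-rate synthesis, short dead time.
tiny_config <- function(n_trials = 4, conditions = "MT_HIGH",
                        eog_rate = 10, ...) {
  simulation_config(
    rate = 128, n_trials = n_trials, conditions = conditions,
    timing = list(cue = 0.3, break_range = c(2, 2), break_ss = 2,
                  orientation = 2.5, action = 3, iti = 1),
    eog = list(rate_per_min = eog_rate, amplitude = 80, decay = 0.3),
    subject_gain = list(mean = 1, sd = 0.15, min = 0.5, fixed = 1),
    ...)
}

# A deterministic little recording: two channels, pure tones.
tone_recording <- function(rate = 512, seconds = 1, freqs = c(10, 37.5),
                           labels = c("C3", "C4")) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  sig <- do.call(rbind, lapply(freqs, function(f) sin(2 * pi * f * t)))
  recording(sig, rate, labels)
}

# Independent naive O(N^2) DFT magnitude oracle (no stats::fft).
naive_dft_amplitude <- function(x) {
  n <- length(x)
  half <- n %/% 2 + 1L
  amp <- numeric(half)
  for (k in seq_len(half) - 1L) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1L) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1L) / n))
    amp[k + 1L] <- sqrt(re^2 + im^2) * 2 / n
  }
  amp[1] <- amp[1] / 2
  if (n %% 2 == 0) amp[half] <- amp[half] / 2
  amp
}
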