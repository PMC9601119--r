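# Shared fixture builders; everything is generated in code at test time.

# Multi-tone epoch with a small noise floor: one narrowband peak per listed
# frequency, so the FBSE spectrum has clear troughs for boundary detection.
tone_epoch <- function(freqs, amps = rep(1, length(freqs)), S = 128,
                       fs = 128, noise_sd = 0.05) {
  t <- (0:(S - 1)) / fs
  x <- numeric(S)
  for (j in seq_along(freqs)) {
    x <- x + amps[j] * sqrt(2) * sin(2 * pi * freqs[j] * t + runif(1, 0, 2 * pi))
  }
  x <- x + rnorm(S, sd = noise_sd)
  x - mean(x)
}

# Tiny trial table built by hand (no generator): sinusoidal channels.
tiny_trials <- function(n_trials = 2, duration_s = 61, n_eeg = 2, n_ecg = 1) {
  rows <- lapply(seq_len(n_trials), function(tr) {
    t_eeg <- (0:(duration_s * 128 - 1)) / 128
    t_ecg <- (0:(duration_s * 256 - 1)) / 256
    eeg <- sapply(seq_len(n_eeg), function(ch) sin(2 * pi * (8 + ch) * t_eeg) + 5)
    ecg <- sapply(seq_len(n_ecg), function(ch) sin(2 * pi * 1.2 * t_ecg) + 2)
    tibble::tibble(
      subject = 1L, trial = tr,
      arousal = c(2L, 5L)[(tr - 1L) %% 2L + 1L],
      valence = 3L, dominance = 4L,
      eeg = list(eeg), ecg = list(ecg)
    )
  })
  dplyr::bind_rows(rows)
}

# Small synthetic spec used across pipeline tests (short trials for speed;
# the 60-s analysis window still fits).
small_spec <- function(...) {
  synthetic_spec(n_subjects = 1, n_trials = 2, duration_s = 61, ...)
}

expect_fbewt_error <- function(expr, class) {
  expect_error(expr, class = class)
}
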