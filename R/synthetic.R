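# Canonical EEG rhythm bands (Hz) and their baseline RMS amplitudes
# (arbitrary microvolt-like units). The class effect multiplies the POWER of
# one band per emotion dimension: arousal -> gamma, valence -> alpha,
# dominance -> beta.
.eeg_bands <- data.frame(
  band = c("delta", "theta", "alpha", "beta", "gamma"),
  lo   = c(1, 4, 8, 13, 30),
  hi   = c(4, 8, 13, 30, 45),
  amp  = c(2, 1, 1.5, 0.8, 0.5)
)

#' Specification of a synthetic DREAMER-shaped dataset
#'
#' Default shape follows the DREAMER study design: 23 subjects, 18
#' audio-visual trials each, 199 s recordings (of which the pipeline
#' analyses the final 60 s), 14 EEG channels at 128 Hz and 2 ECG channels at
#' 256 Hz, with 1-5 ratings per trial on the arousal, valence and dominance
#' scales.
#'
#' EEG channels are sums of narrowband oscillations in the five canonical
#' rhythm bands (tone frequency and phase redrawn independently every 1-s
#' block) plus 1/f (pink) noise of RMS `noise_sd`; ECG channels are Gaussian
#' R-wave pulse trains at a 70 bpm base rate with 5% beat-to-beat jitter.
#' For a "high" trial on a dimension, `class_effect` multiplies the power of
#' that dimension's band (and, for arousal, the heart rate), so the class
#' signal lives in band-power structure rather than raw amplitude. Each
#' 1-s block of band noise is drawn independently, making epoch-level
#' features exchangeable when `class_effect = 1`.
#'
#' @param n_subjects,n_trials Dataset shape (defaults 23 and 18).
#' @param duration_s Trial length in seconds (default 199).
#' @param fs_eeg,fs_ecg Sampling rates in Hz (defaults 128 and 256).
#' @param n_eeg_channels,n_ecg_channels Channel counts (defaults 14 and 2).
#' @param class_effect Band-power multiplier for "high" trials (> 0;
#'   default 2; 1 removes all class information).
#' @param noise_sd RMS of the EEG pink-noise floor, on the scale of the
#'   band amplitudes (delta 2, theta 1, alpha 1.5, beta 0.8, gamma 0.5;
#'   default 0.2, a clean recording whose floor sits below the weakest
#'   rhythm). ECG noise uses `noise_sd / 4`.
#' @param seed Integer seed; identical specs generate identical datasets.
#' @return A `fbewt_synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 23, n_trials = 18, duration_s = 199,
                           fs_eeg = 128, fs_ecg = 256,
                           n_eeg_channels = 14, n_ecg_channels = 2,
                           class_effect = 2, noise_sd = 0.2, seed = 1) {
  counts <- c(n_subjects, n_trials, duration_s, fs_eeg, fs_ecg,
              n_eeg_channels, n_ecg_channels)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop_fbewt("all counts and rates must be positive.",
               "fbewt_invalid_argument")
  }
  if (!is.finite(class_effect) || class_effect <= 0) {
    stop_fbewt("`class_effect` must be > 0.", "fbewt_invalid_argument")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_fbewt("`noise_sd` must be finite and non-negative.",
               "fbewt_invalid_argument")
  }
  structure(
    list(n_subjects = n_subjects, n_trials = n_trials,
         duration_s = duration_s, fs_eeg = fs_eeg, fs_ecg = fs_ecg,
         n_eeg_channels = n_eeg_channels, n_ecg_channels = n_ecg_channels,
         class_effect = class_effect, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "fbewt_synthetic_spec"
  )
}

.trial_seed <- function(spec, subject, trial) {
  (spec$seed + 7919L * ((subject - 1L) * spec$n_trials + (trial - 1L))) %%
    .Machine$integer.max
}

# Balanced class design: for every subject and emotion dimension, exactly
# half of the trials (rounded up) are "high", in an order drawn from a
# subject-level seed. Balance keeps chance-level evaluation centred at 50%
# (k-nearest-neighbour accuracy under no effect is p^2 + (1-p)^2 for class
# share p, i.e. above 50% whenever classes are unbalanced).
.trial_classes <- function(spec, subject, trial) {
  set.seed((spec$seed + 337L * subject) %% .Machine$integer.max)
  vapply(1:3, function(d) {
    n_hi <- ceiling(spec$n_trials / 2)
    hi <- sample(spec$n_trials, n_hi)
    trial %in% hi
  }, logical(1))
}

# Rhythm oscillation for one band, one independent column per 1-s block.
# Baseline: a unit-RMS tone at the band-centre frequency with uniform
# random phase per block, i.e. a narrow stable spectral peak (the troughs
# between band peaks are what boundary detection segments). A class effect
# > 1 multiplies the band's power by `effect` and redistributes it across
# the band: the centre keeps fraction 1/effect, and the excess spreads
# equally over three satellite components inside the band (band
# broadening). The spectral entropies are invariant to pure scaling and to
# bin permutations, so class information must live in the evenness of the
# within-band energy distribution; at effect = 1 the satellites carry
# exactly zero power and the baseline single tone is recovered.
.band_osc_blocks <- function(S, n_blocks, lo, hi, fs, effect = 1) {
  w <- hi - lo
  freqs <- lo + c(0.5, 0.15, 0.65, 0.9) * w
  fracs <- c(1 / effect, rep((1 - 1 / effect) / 3, 3))
  t <- (0:(S - 1)) / fs
  tone <- function(f) {
    phi <- stats::runif(n_blocks, 0, 2 * pi)
    sqrt(2) * sin(outer(2 * pi * f * t, phi, "+"))
  }
  out <- matrix(0, S, n_blocks)
  for (j in seq_along(freqs)) {
    if (fracs[j] > 0) out <- out + sqrt(effect * fracs[j]) * tone(freqs[j])
  }
  out
}

# 1/f noise with the requested RMS, independent per 1-s block.
.pink_noise_blocks <- function(S, n_blocks, rms) {
  if (rms <= 0) return(matrix(0, S, n_blocks))
  w <- matrix(stats::rnorm(S * n_blocks), S, n_blocks)
  f <- (0:(S - 1))
  f <- pmin(f, S - f)
  g <- ifelse(f > 0, 1 / sqrt(f), 0)
  X <- stats::mvfft(w) * g
  p <- Re(stats::mvfft(X, inverse = TRUE)) / S
  r <- sqrt(colMeans(p^2))
  r[r == 0] <- 1
  sweep(p, 2, rms / r, "*")
}

# Gaussian R-wave pulse train, generated one independent 1-s block at a
# time: each block gets a regular beat comb at the requested rate with a
# uniform random phase and per-beat timing jitter. Independent blocks keep
# epoch-level features exchangeable when there is no class effect.
.ecg_channel <- function(duration_s, fs, rate_bpm, jitter = 0.03,
                         amp = 1, noise_sd = 0.05) {
  ibi <- 60 / rate_bpm
  sigma <- 0.015                              # R-wave width in seconds
  tt <- (0:(fs - 1)) / fs
  sig <- matrix(stats::rnorm(fs * duration_s, sd = noise_sd), fs, duration_s)
  for (b in seq_len(duration_s)) {
    beats <- seq(stats::runif(1, 0, ibi), 1, by = ibi)
    beats <- beats + jitter * ibi * stats::rnorm(length(beats))
    for (tb in beats) {
      sig[, b] <- sig[, b] + amp * exp(-(tt - tb)^2 / (2 * sigma^2))
    }
  }
  as.vector(sig)
}

#' Generate one synthetic trial
#'
#' Deterministic given `(spec, subject, trial)`: the trial's ratings and
#' signals are drawn from a seed derived from the spec seed and the trial
#' coordinates, so a dataset can be generated trial-by-trial in any order.
#'
#' @param spec A [synthetic_spec()].
#' @param subject,trial 1-based coordinates within the design.
#' @return A one-row tibble with columns `subject`, `trial`, `arousal`,
#'   `valence`, `dominance` (integer ratings 1-5) and list columns `eeg`
#'   (samples x channels matrix at `fs_eeg`) and `ecg` (samples x channels
#'   at `fs_ecg`).
#' @export
generate_trial <- function(spec, subject, trial) {
  stopifnot(inherits(spec, "fbewt_synthetic_spec"))
  cls <- .trial_classes(spec, subject, trial)  # arousal, valence, dominance
  set.seed(.trial_seed(spec, subject, trial))
  # ratings consistent with the threshold-3 labelling of the class
  ratings <- ifelse(cls, sample(4:5, 3, replace = TRUE),
                    sample(1:3, 3, replace = TRUE))
  S <- spec$fs_eeg
  n_blocks <- spec$duration_s
  band_amp <- .eeg_bands$amp
  # disjoint band signatures over the three bands wide enough to carry a
  # within-band power redistribution: arousal -> gamma (plus heart rate
  # below), valence -> alpha, dominance -> beta
  effect <- rep(1, 5)
  if (cls[1]) effect[5] <- spec$class_effect
  if (cls[2]) effect[3] <- spec$class_effect
  if (cls[3]) effect[4] <- spec$class_effect
  eeg <- matrix(0, S * n_blocks, spec$n_eeg_channels)
  for (ch in seq_len(spec$n_eeg_channels)) {
    sig <- .pink_noise_blocks(S, n_blocks, spec$noise_sd)
    for (b in seq_len(nrow(.eeg_bands))) {
      sig <- sig + band_amp[b] *
        .band_osc_blocks(S, n_blocks, .eeg_bands$lo[b], .eeg_bands$hi[b],
                         spec$fs_eeg, effect[b])
    }
    if (effect[5] > 1) {
      # high-arousal gamma activity extends into the high-gamma range
      # (45-60 Hz) with power (class_effect - 1) x baseline gamma power;
      # exactly zero under the null.
      sig <- sig + band_amp[5] * sqrt(effect[5] - 1) *
        .band_osc_blocks(S, n_blocks, 45, 60, spec$fs_eeg)
    }
    eeg[, ch] <- as.vector(sig)
  }
  rate <- 70 * if (cls[1]) spec$class_effect else 1
  ecg <- vapply(seq_len(spec$n_ecg_channels), function(ch) {
    .ecg_channel(spec$duration_s, spec$fs_ecg, rate,
                 amp = c(1, 0.8)[(ch - 1L) %% 2L + 1L],
                 noise_sd = spec$noise_sd / 4)
  }, numeric(spec$duration_s * spec$fs_ecg))
  tibble::tibble(
    subject = as.integer(subject), trial = as.integer(trial),
    arousal = as.integer(ratings[1]), valence = as.integer(ratings[2]),
    dominance = as.integer(ratings[3]),
    eeg = list(eeg), ecg = list(matrix(ecg, ncol = spec$n_ecg_channels))
  )
}

#' Generate a full synthetic dataset
#'
#' Loops [generate_trial()] over the subject-by-trial design and binds the
#' rows. The default spec yields 23 x 18 = 414 trials whose preprocessed
#' epochs form the 24,840-row feature matrix of the full study shape.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with one row per trial (see [generate_trial()]).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "fbewt_synthetic_spec"))
  grid <- expand.grid(trial = seq_len(spec$n_trials),
                      subject = seq_len(spec$n_subjects))
  purrr::map2_dfr(grid$subject, grid$trial,
                  function(s, t) generate_trial(spec, s, t))
}
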