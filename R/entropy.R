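.check_energy <- function(E) {
  if (!is.numeric(E) || length(E) == 0) {
    stop_fbewt("energy spectrum must be a non-empty numeric vector.",
               "fbewt_invalid_argument")
  }
  if (any(!is.finite(E)) || any(E < 0)) {
    stop_fbewt("energy spectrum must be finite and non-negative.",
               "fbewt_invalid_input")
  }
  if (sum(E) <= 0) {
    stop_fbewt("degenerate input: energy spectrum is identically zero.",
               "fbewt_degenerate_input")
  }
  E
}

.normalize_energy <- function(E) E / sum(E)

#' Shannon spectral entropy of a Fourier-Bessel energy spectrum
#'
#' \eqn{H_{SSE} = -\sum_i P(i) \log_2 P(i)} with
#' \eqn{P(i) = E_i / \sum_i E_i} and the convention
#' \eqn{0 \log 0 = 0}. Measures how uniformly the epoch's energy spreads over
#' the FB orders: 0 for a single occupied bin, \eqn{\log_2 S} for a flat
#' spectrum.
#'
#' @param E Non-negative numeric vector (e.g. from [energy_spectrum()]) with
#'   positive total energy.
#' @return Entropy in bits, in `[0, log2(length(E))]`.
#' @export
shannon_spectral_entropy <- function(E) {
  if (inherits(E, "fbse_spectrum")) E <- energy_spectrum(E)
  E <- .check_energy(E)
  P <- .normalize_energy(E)
  nz <- P > 0
  -sum(P[nz] * log2(P[nz]))
}

#' Wiener entropy (spectral flatness) of a Fourier-Bessel energy spectrum
#'
#' The ratio of the geometric to the arithmetic mean of the energy spectrum:
#' \deqn{H_{WE} = \frac{\left(\prod_i E_i\right)^{1/S}}{\frac{1}{S}\sum_i E_i}.}
#' Dimensionless in `[0, 1]` by the AM-GM inequality: 1 for a uniform (flat)
#' spectrum, 0 for a pure tone. Computed as the exponential of the mean log
#' energy; entries below 1e-300 are treated as exact zeros, and any zero
#' forces the geometric mean — hence the result — to 0.
#'
#' @inheritParams shannon_spectral_entropy
#' @return A number in `[0, 1]`.
#' @examples
#' wiener_entropy(rep(3, 64))   # flat spectrum -> 1
#' wiener_entropy(c(5, rep(0, 63))) # pure tone -> 0
#' @export
wiener_entropy <- function(E) {
  if (inherits(E, "fbse_spectrum")) E <- energy_spectrum(E)
  E <- .check_energy(E)
  if (any(E < 1e-300)) {
    return(0)
  }
  exp(mean(log(E))) / mean(E)
}

#' Log energy entropy of a Fourier-Bessel energy spectrum
#'
#' \eqn{H_{LE} = -\sum_i \log_2 P(i)} over the normalised energy
#' distribution. The sum diverges when any \eqn{P(i) = 0}, so probabilities
#' are floored at `floor` before taking logs (default `1e-12`).
#'
#' @inheritParams shannon_spectral_entropy
#' @param floor Positive lower bound applied to each `P(i)` (default 1e-12).
#' @return A non-negative number.
#' @export
log_energy_entropy <- function(E, floor = 1e-12) {
  if (inherits(E, "fbse_spectrum")) E <- energy_spectrum(E)
  E <- .check_energy(E)
  if (length(floor) != 1L || !is.finite(floor) || floor <= 0) {
    stop_fbewt("`floor` must be a single positive number.",
               "fbewt_invalid_argument")
  }
  P <- pmax(.normalize_energy(E), floor)
  -sum(log2(P))
}

#' The three Fourier-Bessel entropies of one narrow-band mode
#'
#' Re-expands a reconstructed mode over the full epoch length with
#' [fbse_transform()], forms its FB energy spectrum and evaluates the
#' Shannon spectral entropy, Wiener entropy and log energy entropy. This is
#' the per-mode feature triple the classification pipeline assembles.
#'
#' An all-zero mode has no energy distribution; its entropies are returned
#' as `NA` and the pipeline decides how to handle the row.
#'
#' @param mode Numeric vector (one reconstructed mode).
#' @param fs Sampling rate in Hz.
#' @param floor Probability floor for the log energy entropy.
#' @param method FBSE analysis rule, see [fbse_transform()].
#' @return Named numeric vector `c(sse = , we = , lee = )`.
#' @export
fb_mode_entropies <- function(mode, fs, floor = 1e-12,
                              method = c("collocation", "quadrature")) {
  method <- match.arg(method)
  if (all(mode == 0)) {
    return(c(sse = NA_real_, we = NA_real_, lee = NA_real_))
  }
  E <- energy_spectrum(fbse_transform(mode, fs, method = method))
  c(
    sse = shannon_spectral_entropy(E),
    we = wiener_entropy(E),
    lee = log_energy_entropy(E, floor = floor)
  )
}
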