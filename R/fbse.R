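#' Positive roots of the zero-order Bessel function
#'
#' Computes the first `S` positive roots \eqn{\beta_i} of \eqn{J_0}. Each root
#' is seeded at its asymptotic location \eqn{i\pi} and refined by Newton's
#' method using the identity \eqn{J_0' = -J_1}, so the returned values are
#' accurate well beyond the \eqn{\beta_i \approx i\pi} approximation that
#' motivates the order-to-frequency map.
#'
#' @param S Number of roots (positive integer).
#' @return Numeric vector of length `S`, strictly increasing; the first
#'   element is 2.4048255577 and consecutive differences approach \eqn{\pi}.
#' @examples
#' bessel_j0_roots(3)
#' @export
bessel_j0_roots <- function(S) {
  if (length(S) != 1L || !is.finite(S) || S < 1 || S != round(S)) {
    stop_fbewt("`S` must be a single positive integer.", "fbewt_invalid_argument")
  }
  S <- as.integer(S)
  x <- (seq_len(S)) * pi
  # Newton: x <- x + J0(x)/J1(x); converges quadratically from the i*pi seed.
  for (iter in 1:8) {
    step <- besselJ(x, 0) / besselJ(x, 1)
    x <- x + step
    if (max(abs(step)) < 1e-13) break
  }
  x
}

# Cache of per-length basis matrices and their inverses, keyed by S.
.fbse_cache <- new.env(parent = emptyenv())

.fbse_basis <- function(S) {
  key <- as.character(S)
  if (!is.null(.fbse_cache[[key]])) {
    return(.fbse_cache[[key]])
  }
  roots <- bessel_j0_roots(S)
  n <- 0:(S - 1)
  # B[n+1, i] = J0(beta_i * n / S): the synthesis (collocation) matrix.
  B <- outer(n / S, roots, function(t, b) besselJ(b * t, 0))
  j1sq <- besselJ(roots, 1)^2
  env <- list(
    roots = roots,
    B = B,
    Binv = solve(B),
    j1sq = j1sq,
    # Row weights of the printed analysis quadrature: K = W %*% s.
    Wq = t(B * n) * (2 / (S^2 * j1sq))
  )
  .fbse_cache[[key]] <- env
  env
}

#' Fourier-Bessel series expansion of a finite signal
#'
#' Expands an `S`-sample signal on the zero-order Bessel basis
#' \eqn{J_0(\beta_i n/S)}, \eqn{i = 1..S}, giving a spectrum with `S` points
#' over \eqn{[0, f_s/2]} — twice the bin density of the half-spectrum DFT of
#' the same window.
#'
#' Two analysis rules are available. `"collocation"` (the default) solves the
#' synthesis system \eqn{s(n) = \sum_i K(i) J_0(\beta_i n/S)} exactly, so
#' [fbse_synthesize()] reconstructs the signal to machine precision; the
#' system is well conditioned (condition number below ~40 for all window
#' lengths used here). `"quadrature"` evaluates the explicit coefficient
#' formula
#' \deqn{K(i) = \frac{2}{S^2 J_1(\beta_i)^2} \sum_{n=0}^{S-1} n\, s(n)\,
#'   J_0(\beta_i n/S),}
#' the uniform-grid discretisation of the continuous Bessel orthogonality
#' relation; it is the classical printed form but only approximately
#' invertible on a uniform grid.
#'
#' @param signal Numeric vector of length at least 2, all values finite.
#' @param fs Sampling rate in Hz.
#' @param method `"collocation"` (exact discrete transform, default) or
#'   `"quadrature"` (explicit weighted-sum formula).
#' @return An object of class `fbse_spectrum`: list with `coefficients`
#'   (length `S`), `roots`, `fs`, `S`, `freq_grid` (Hz, strictly increasing,
#'   ending at `fs/2`) and `method`.
#' @seealso [fbse_synthesize()], [energy_spectrum()], [order_to_frequency()]
#' @examples
#' sp <- fbse_transform(sin(2 * pi * 10 * (0:127) / 128), fs = 128)
#' sp$freq_grid[which.max(abs(sp$coefficients))]
#' @export
fbse_transform <- function(signal, fs, method = c("collocation", "quadrature")) {
  method <- match.arg(method)
  if (!is.numeric(signal) || length(signal) < 2) {
    stop_fbewt("`signal` must be a numeric vector of length >= 2.",
               "fbewt_invalid_argument")
  }
  if (any(!is.finite(signal))) {
    stop_fbewt("`signal` contains non-finite samples.", "fbewt_invalid_input")
  }
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop_fbewt("`fs` must be a single positive number.", "fbewt_invalid_argument")
  }
  S <- length(signal)
  bs <- .fbse_basis(S)
  K <- if (method == "collocation") {
    as.vector(bs$Binv %*% signal)
  } else {
    as.vector(bs$Wq %*% signal)
  }
  structure(
    list(
      coefficients = K,
      roots = bs$roots,
      fs = fs,
      S = S,
      freq_grid = order_to_frequency(seq_len(S), S, fs),
      method = method
    ),
    class = "fbse_spectrum"
  )
}

#' Reconstruct a signal from its Fourier-Bessel spectrum
#'
#' Evaluates the zero-order synthesis sum
#' \eqn{s(n) = \sum_{i=1}^{S} K(i) J_0(\beta_i n/S)} on the original sample
#' grid. For spectra computed with `method = "collocation"` this inverts
#' [fbse_transform()] to machine precision.
#'
#' @param spec An `fbse_spectrum`.
#' @return Numeric vector of length `spec$S`.
#' @export
fbse_synthesize <- function(spec) {
  stopifnot(inherits(spec, "fbse_spectrum"))
  bs <- .fbse_basis(spec$S)
  as.vector(bs$B %*% spec$coefficients)
}

#' Map a Fourier-Bessel order to continuous frequency
#'
#' Under the asymptotic root spacing \eqn{\beta_i \approx i\pi}, order `i` of
#' an `S`-sample window at rate `fs` corresponds to
#' \eqn{f_i = i\, f_s / (2S)} Hz, so orders `1..S` tile \eqn{(0, f_s/2]}.
#'
#' @param i Order(s), each in `1..S`.
#' @param S Window length in samples.
#' @param fs Sampling rate in Hz.
#' @return Frequency in Hz, same length as `i`; monotone in `i`.
#' @examples
#' order_to_frequency(2, S = 128, fs = 128) # 1 Hz
#' @export
order_to_frequency <- function(i, S, fs) {
  if (any(i < 1 | i > S)) {
    stop_fbewt("order `i` must lie in [1, S].", "fbewt_invalid_argument")
  }
  i * fs / (2 * S)
}

#' Fourier-Bessel energy spectrum
#'
#' Energy of each FB coefficient,
#' \deqn{E_i = \frac{K(i)^2\, S^2\, J_1(\beta_i)^2}{2},}
#' the discrete Parseval weight of the zero-order basis. This is the input
#' to the spectral entropies ([shannon_spectral_entropy()],
#' [wiener_entropy()], [log_energy_entropy()]).
#'
#' @param spec An `fbse_spectrum`.
#' @return Numeric vector of length `spec$S`, all entries non-negative.
#' @export
energy_spectrum <- function(spec) {
  stopifnot(inherits(spec, "fbse_spectrum"))
  bs <- .fbse_basis(spec$S)
  spec$coefficients^2 * spec$S^2 * bs$j1sq / 2
}

#' @export
print.fbse_spectrum <- function(x, ...) {
  cat(sprintf(
    "<fbse_spectrum> S = %d, fs = %g Hz, method = %s\n  freq grid: %.3g .. %.3g Hz, peak |K| at %.3g Hz\n",
    x$S, x$fs, x$method, x$freq_grid[1], x$freq_grid[x$S],
    x$freq_grid[which.max(abs(x$coefficients))]
  ))
  invisible(x)
}
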