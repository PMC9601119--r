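#' Meyer auxiliary (transition) polynomial
#'
#' The standard degree-7 Meyer window polynomial
#' \eqn{\delta(x) = x^4(35 - 84x + 70x^2 - 20x^3)} on \eqn{(0,1)}, clamped to
#' 0 below and 1 above. It satisfies \eqn{\delta(x) + \delta(1-x) = 1} on
#' `[0, 1]`, which is what makes the squared filter responses sum to one
#' across a transition band.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, in `[0, 1]`.
#' @examples
#' meyer_auxiliary(c(-1, 0.3, 0.5, 0.7, 2))
#' @export
meyer_auxiliary <- function(x) {
  y <- pmin(pmax(x, 0), 1)
  y^4 * (35 - 84 * y + 70 * y^2 - 20 * y^3)
}

# Transition argument: delta((w - (1 - tau) wj) / (2 tau wj)).
.transition <- function(w, wj, tau) {
  meyer_auxiliary((w - (1 - tau) * wj) / (2 * tau * wj))
}

# Scaling response: 1 up to (1-tau)w1, cosine roll-off, 0 above.
.phi_response <- function(w, w1, tau) {
  cos(pi / 2 * .transition(w, w1, tau))
}

# Wavelet response between boundaries w_lo and w_hi; w_hi = NA means the
# last (high-pass) wavelet, which holds 1 up to the Nyquist edge pi.
.nu_response <- function(w, w_lo, w_hi, tau) {
  r <- sin(pi / 2 * .transition(w, w_lo, tau))
  if (!is.na(w_hi)) {
    r <- r * cos(pi / 2 * .transition(w, w_hi, tau))
  }
  r
}

.tau_bound <- function(omegas) {
  w <- c(omegas, pi)
  min(diff(w) / (w[-1] + w[-length(w)]))
}

#' Build the empirical wavelet filter bank on detected boundaries
#'
#' Constructs the Meyer-type scaling response \eqn{\Phi_1(\omega)} (low-pass
#' up to the first boundary) and wavelet responses \eqn{\nu_j(\omega)} (one
#' per band between consecutive boundaries; the last is high-pass to
#' \eqn{\pi}) on the normalised frequency axis. Each response is 1 on its
#' plateau, rolls off through cosine/sine transitions of relative half-width
#' `tau` around each boundary, and 0 elsewhere, so that
#' \eqn{\Phi_1^2 + \sum_j \nu_j^2 = 1} everywhere on \eqn{[0, \pi]} (tight
#' frame / partition of unity).
#'
#' `tau` must respect the non-overlap (frame) condition
#' \eqn{\tau < \min_j (\omega_{j+1}-\omega_j)/(\omega_{j+1}+\omega_j)}
#' (boundary list augmented with \eqn{\pi}); when omitted it is set to 0.9
#' times that bound.
#'
#' @param omegas An `fbewt_boundaries` object or a sorted numeric vector of
#'   boundaries in \eqn{(0, \pi)}.
#' @param tau Transition half-width (relative); default 0.9 of the frame
#'   bound.
#' @param grid_size Number of points of the dense `[0, pi]` evaluation grid
#'   stored for inspection/plotting (default 512). Decomposition evaluates
#'   the responses analytically at each epoch's own Fourier bins, so the
#'   grid is cosmetic.
#' @return An object of class `fbewt_bank`: list with `omegas`, `tau`, `M`
#'   (number of wavelet responses), `grid`, `phi` (scaling response on the
#'   grid) and `nus` (grid_size x M matrix of wavelet responses).
#' @seealso [ewt_decompose()], [detect_boundaries()]
#' @export
build_filter_bank <- function(omegas, tau = NULL, grid_size = 512) {
  if (inherits(omegas, "fbewt_boundaries")) omegas <- omegas$omegas
  if (!is.numeric(omegas) || length(omegas) < 1 ||
      any(omegas <= 0 | omegas >= pi) || is.unsorted(omegas, strictly = TRUE)) {
    stop_fbewt("`omegas` must be strictly increasing and inside (0, pi).",
               "fbewt_invalid_argument")
  }
  bound <- .tau_bound(omegas)
  if (is.null(tau)) {
    tau <- 0.9 * bound
  } else if (tau <= 0 || tau >= bound) {
    stop_fbewt(sprintf(
      "frame condition violated: tau must lie in (0, %.4f) for these boundaries.",
      bound), "fbewt_invalid_argument")
  }
  M <- length(omegas)
  grid <- seq(0, pi, length.out = grid_size)
  nus <- vapply(seq_len(M), function(j) {
    .nu_response(grid, omegas[j], if (j < M) omegas[j + 1] else NA_real_, tau)
  }, numeric(grid_size))
  structure(
    list(
      omegas = omegas, tau = tau, M = M,
      grid = grid,
      phi = .phi_response(grid, omegas[1], tau),
      nus = matrix(nus, ncol = M)
    ),
    class = "fbewt_bank"
  )
}

# Squared responses of a bank evaluated at the (folded) FFT bin frequencies
# of an S-sample epoch: S x (M + 1) matrix, first column the scaling filter.
.bank_gains_fft <- function(omegas, tau, S) {
  w <- 2 * pi * (0:(S - 1)) / S
  w <- pmin(w, 2 * pi - w)  # fold to [0, pi]; keeps modes real-valued
  M <- length(omegas)
  g <- matrix(0, S, M + 1L)
  g[, 1] <- .phi_response(w, omegas[1], tau)^2
  for (j in seq_len(M)) {
    g[, j + 1] <- .nu_response(w, omegas[j],
                               if (j < M) omegas[j + 1] else NA_real_, tau)^2
  }
  g
}

#' Decompose an epoch into empirical wavelet modes
#'
#' Filters the epoch through the bank in the frequency domain: the detail
#' (wavelet) and approximation (scaling) coefficients are obtained by
#' multiplying the epoch's Fourier transform with the conjugated response,
#' and each mode is that result convolved once more with the same response —
#' equivalently, multiplication by the squared frequency response, treating
#' the convolutions as circular on the epoch length. Responses act
#' symmetrically on negative frequencies so every mode is real. Because the
#' squared responses form a partition of unity, the low-frequency component
#' plus all modes reconstruct the epoch.
#'
#' @param epoch Numeric vector, length >= 8.
#' @param bank An `fbewt_bank`.
#' @return An object of class `fbewt_modes`: list with `r0` (low-frequency
#'   component), `modes` (length(epoch) x M matrix, one narrow-band mode per
#'   column), `M`, `omegas` and `tau`.
#' @examples
#' bank <- build_filter_bank(pi / 2, tau = 0.1)
#' md <- ewt_decompose(sin(2 * pi * 50 * (0:127) / 128), bank)
#' @export
ewt_decompose <- function(epoch, bank) {
  stopifnot(inherits(bank, "fbewt_bank"))
  if (!is.numeric(epoch) || length(epoch) < 8) {
    stop_fbewt("`epoch` must be numeric with length >= 8.",
               "fbewt_invalid_input")
  }
  S <- length(epoch)
  gains <- .bank_gains_fft(bank$omegas, bank$tau, S)
  X <- stats::fft(epoch)
  comp <- vapply(seq_len(ncol(gains)), function(j) {
    Re(stats::fft(X * gains[, j], inverse = TRUE)) / S
  }, numeric(S))
  structure(
    list(
      r0 = comp[, 1],
      modes = matrix(comp[, -1, drop = FALSE], nrow = S),
      M = bank$M,
      omegas = bank$omegas,
      tau = bank$tau
    ),
    class = "fbewt_modes"
  )
}

#' All components of a mode decomposition as one matrix
#'
#' Returns the low-frequency component and the wavelet modes side by side
#' (columns `mode1..mode{M+1}`, lowest band first). These M + 1 narrow-band
#' components are what the feature pipeline calls the "modes" of an epoch:
#' with the default 3 boundaries an epoch yields 4 modes.
#'
#' @param x An `fbewt_modes` object.
#' @return Numeric matrix, epoch length x (M + 1), with column names.
#' @export
mode_matrix <- function(x) {
  stopifnot(inherits(x, "fbewt_modes"))
  m <- cbind(x$r0, x$modes)
  colnames(m) <- paste0("mode", seq_len(ncol(m)))
  m
}

#' @export
print.fbewt_bank <- function(x, ...) {
  cat(sprintf("<fbewt_bank> %d wavelet bands, tau = %.4f, boundaries: %s\n",
              x$M, x$tau,
              paste(sprintf("%.3f*pi", x$omegas / pi), collapse = ", ")))
  invisible(x)
}

#' @export
print.fbewt_modes <- function(x, ...) {
  cat(sprintf("<fbewt_modes> %d components (r0 + %d modes), epoch length %d\n",
              x$M + 1L, x$M, length(x$r0)))
  invisible(x)
}
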