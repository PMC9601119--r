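#' Gaussian scale-space of a magnitude spectrum
#'
#' Smooths a non-negative magnitude spectrum with Gaussian kernels of
#' increasing scale \eqn{q = \varepsilon q_0}, \eqn{\varepsilon = 1..
#' \varepsilon_{max}}, each kernel truncated at half-width
#' \eqn{N = \lfloor W\sqrt{q} \rfloor + 1} (with \eqn{3 \le W \le 6}), and
#' tracks the surviving interior local minima across scales. Minima can only
#' disappear as the scale grows; the number of scales a minimum survives is
#' its *persistence*, the quantity later thresholded by [otsu_threshold()]
#' to separate meaningful band boundaries from noise-induced dips.
#'
#' The spectrum is zero-padded for the convolution, and minima are strict
#' interior minima of the smoothed curve. Tracks are seeded at the finest
#' scale and followed greedily to the nearest minimum at each coarser scale.
#'
#' @param magnitude Non-negative numeric vector, length >= 4.
#' @param q0 Initial scale step (default 0.5).
#' @param eps_max Cap on the number of scale steps; by default the full
#'   geometric schedule is used (scales `q0 * 1.25^(eps-1)` up to the scale
#'   that merges any trough of the spectrum, about 37 steps for a 128-bin
#'   spectrum), so that every minima track dies within the schedule and its
#'   death scale ranks the troughs.
#' @param W Kernel half-width factor in `[3, 6]` (default 5).
#' @return An object of class `fbewt_scalespace`: list with `q0`, `eps_max`,
#'   `W`, `minima_by_scale` (list of integer index vectors, one per scale)
#'   and `tracks`, a tibble with columns `index` (spectral index at the
#'   finest scale) and `persistence` (number of scales survived).
#' @export
gaussian_scale_space <- function(magnitude, q0 = 0.5, eps_max = NULL, W = 5) {
  if (!is.numeric(magnitude) || length(magnitude) < 4) {
    stop_fbewt("`magnitude` must be numeric with length >= 4.",
               "fbewt_invalid_argument")
  }
  S <- length(magnitude)
  if (!is.null(eps_max) && eps_max < 1) {
    stop_fbewt("`eps_max` must be >= 1.", "fbewt_invalid_argument")
  }
  if (W < 3 || W > 6) {
    stop_fbewt("`W` must lie in [3, 6].", "fbewt_invalid_argument")
  }
  res <- .scale_space_tracks(magnitude, q0, eps_max, W)
  structure(
    list(
      q0 = q0, eps_max = length(.scale_schedule(S, q0, eps_max)), W = W,
      minima_by_scale = res$minima_by_scale,
      tracks = tibble::tibble(index = res$index, persistence = res$persistence)
    ),
    class = "fbewt_scalespace"
  )
}

# Strict interior local minima of a numeric vector (1-based indices).
.local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  core <- x[2:(n - 1)]
  which(core < x[1:(n - 2)] & core < x[3:n]) + 1L
}

.gauss_kernel <- function(q, W) {
  N <- floor(W * sqrt(q)) + 1
  n <- -N:N
  g <- exp(-n^2 / (2 * q))
  g / sum(g)
}

# Geometric scale schedule from q0 up to the scale that merges any trough
# of an S-bin spectrum (sd ~ S/3). A geometric ladder keeps the step count
# modest while still resolving death scales over three orders of magnitude;
# persistence is the number of schedule steps a minimum survives.
.scale_schedule <- function(S, q0, eps_max = NULL) {
  q_max <- (S / 3)^2
  n <- ceiling(log(q_max / q0) / log(1.25)) + 1L
  if (!is.null(eps_max)) n <- min(n, eps_max)
  q0 * 1.25^(0:(n - 1L))
}

# Cached stack of zero-padded Gaussian convolution matrices, one S x S
# block per scale, so all scales of all epochs smooth in one BLAS multiply.
.scalespace_cache <- new.env(parent = emptyenv())

.smoothing_stack <- function(S, q0, eps_max, W) {
  key <- paste(S, q0, eps_max, W, sep = "|")
  if (!is.null(.scalespace_cache[[key]])) {
    return(.scalespace_cache[[key]])
  }
  qs <- .scale_schedule(S, q0, eps_max)
  lag <- outer(seq_len(S), seq_len(S), "-")
  blocks <- lapply(qs, function(q) {
    N <- floor(W * sqrt(q)) + 1
    k <- .gauss_kernel(q, W)
    C <- matrix(0, S, S)
    inside <- abs(lag) <= N
    C[inside] <- k[lag[inside] + N + 1L]
    C
  })
  st <- do.call(rbind, blocks)
  .scalespace_cache[[key]] <- st
  st
}

# Per-scale interior minima for every column of a magnitude matrix.
# Returns list[epoch][scale] of integer index vectors.
.scale_space_minima <- function(M, q0, eps_max, W) {
  S <- nrow(M)
  n_scales <- length(.scale_schedule(S, q0, eps_max))
  SM <- .smoothing_stack(S, q0, eps_max, W) %*% M
  out <- lapply(seq_len(ncol(M)), function(j) vector("list", n_scales))
  for (eps in seq_len(n_scales)) {
    block <- SM[((eps - 1L) * S + 1L):(eps * S), , drop = FALSE]
    core <- block[2:(S - 1), , drop = FALSE]
    is_min <- core < block[1:(S - 2), , drop = FALSE] &
      core < block[3:S, , drop = FALSE]
    for (j in seq_len(ncol(M))) {
      out[[j]][[eps]] <- which(is_min[, j]) + 1L
    }
  }
  out
}

# Greedy nearest-neighbour tracking of minima across scales: each minimum at
# the next scale claims the closest live track; a track keeps its nearest
# claimant; unmatched tracks die. Persistence = number of scales survived.
.track_from_minima <- function(minima_by_scale) {
  m1 <- minima_by_scale[[1]]
  pos <- m1
  first <- m1
  persistence <- rep(1L, length(m1))
  alive <- rep(TRUE, length(m1))
  for (eps in seq_along(minima_by_scale)[-1]) {
    live <- which(alive)
    if (length(live) == 0L) break
    m <- minima_by_scale[[eps]]
    matched <- rep(FALSE, length(live))
    if (length(m) > 0L) {
      claim <- rep(NA_integer_, length(live))
      claim_d <- rep(Inf, length(live))
      for (j in seq_along(m)) {
        d <- abs(pos[live] - m[j])
        t <- which.min(d)
        if (d[t] < claim_d[t]) {
          claim[t] <- m[j]
          claim_d[t] <- d[t]
        }
      }
      matched <- !is.na(claim)
      pos[live[matched]] <- claim[matched]
      persistence[live[matched]] <- persistence[live[matched]] + 1L
    }
    alive[live[!matched]] <- FALSE
  }
  list(index = first, persistence = persistence)
}

# Core scale-space minima tracker shared by the user-facing wrapper and the
# pipeline hot path. Returns first-scale indices and persistences.
.scale_space_tracks <- function(magnitude, q0, eps_max, W, keep_minima = TRUE) {
  minima <- .scale_space_minima(matrix(magnitude, ncol = 1), q0, eps_max, W)[[1]]
  tr <- .track_from_minima(minima)
  list(index = tr$index, persistence = tr$persistence,
       minima_by_scale = if (keep_minima) minima else NULL)
}

#' Otsu threshold over persistence lengths
#'
#' Exhaustively scans candidate thresholds (midpoints between distinct
#' observed values) and returns the one maximising the between-class
#' variance of the induced two-class split — Otsu's criterion applied to
#' the empirical histogram of minima-track persistences. Tracks whose
#' persistence exceeds the threshold are considered meaningful boundaries.
#'
#' If all lengths are equal the histogram has a single class; the value
#' minus one half-step is returned so that every track passes.
#'
#' @param lengths Positive numeric (typically integer) vector.
#' @return A single numeric threshold.
#' @examples
#' otsu_threshold(c(1, 1, 1, 10, 10, 10))
#' @export
otsu_threshold <- function(lengths) {
  if (length(lengths) == 0L || !is.numeric(lengths)) {
    stop_fbewt("`lengths` must be a non-empty numeric vector.",
               "fbewt_invalid_argument")
  }
  u <- sort(unique(lengths))
  if (length(u) == 1L) {
    return(u - 0.5)
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- cand[1]
  best_v <- -Inf
  n <- length(lengths)
  for (thr in cand) {
    lo <- lengths[lengths <= thr]
    hi <- lengths[lengths > thr]
    w0 <- length(lo) / n
    w1 <- length(hi) / n
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) {
      best_v <- v
      best <- thr
    }
  }
  best
}

# Boundary selection given tracked minima: Otsu threshold on persistence,
# rank the survivors, supplement by equal-width splitting when short.
.select_boundaries <- function(tr, n_modes_requested, S) {
  n_b <- n_modes_requested - 1L
  idx <- integer(0)
  if (length(tr$index) > 0L) {
    thr <- otsu_threshold(tr$persistence)
    keep <- tr$persistence > thr
    cand_idx <- tr$index[keep]
    cand_per <- tr$persistence[keep]
    # rank by persistence (desc), ties broken by lower frequency
    ord <- order(-cand_per, cand_idx)
    idx <- utils::head(cand_idx[ord], n_b)
    # interior only
    idx <- idx[idx > 1L & idx < S]
  }
  idx <- sort(unique(idx))
  # Fewer persistent minima than requested: split the widest band until the
  # requested count is reached (equal-width supplement).
  while (length(idx) < n_b) {
    edges <- c(0L, idx, S)
    gaps <- diff(edges)
    g <- which.max(gaps)
    mid <- as.integer(round((edges[g] + edges[g + 1]) / 2))
    mid <- min(max(mid, 1L), S - 1L)
    if (mid %in% idx || mid < 1L) break
    idx <- sort(c(idx, mid))
  }
  idx
}

# Boundary spectral indices for one magnitude spectrum.
.boundaries_for_magnitude <- function(magnitude, n_modes_requested,
                                      q0 = 0.5, eps_max = NULL, W = 5) {
  S <- length(magnitude)
  tr <- .scale_space_tracks(magnitude, q0, eps_max, W, keep_minima = FALSE)
  .select_boundaries(tr, n_modes_requested, S)
}

# Batched variant: one column per epoch; returns a list of index vectors.
.boundaries_for_matrix <- function(M, n_modes_requested,
                                   q0 = 0.5, eps_max = NULL, W = 5) {
  S <- nrow(M)
  minima <- .scale_space_minima(M, q0, eps_max, W)
  lapply(minima, function(mm) {
    .select_boundaries(.track_from_minima(mm), n_modes_requested, S)
  })
}

#' Detect spectral band boundaries on the FBSE magnitude spectrum
#'
#' Segments the magnitude spectrum \eqn{|K(i)|} into `n_modes_requested`
#' contiguous bands over the normalised frequency axis \eqn{[0, \pi]}.
#' Boundaries are the persistent local minima of the Gaussian scale-space
#' ([gaussian_scale_space()]) whose persistence exceeds the Otsu threshold;
#' when more survive than needed, the most persistent are kept (ties broken
#' towards lower frequency), and when fewer survive, the widest band is
#' split at its midpoint until the requested count is reached. A boundary at
#' spectral index `i` maps to \eqn{\omega = \pi i / S}.
#'
#' @param spec An `fbse_spectrum` (its `|K(i)|` is analysed), or a
#'   non-negative numeric magnitude vector.
#' @param n_modes_requested Number of bands wanted (>= 2; default 4).
#' @param q0,eps_max,W Scale-space parameters, see [gaussian_scale_space()].
#' @return An object of class `fbewt_boundaries`: list with `omegas`
#'   (sorted, strictly inside \eqn{(0, \pi)}), `indices` (spectral indices),
#'   `n_modes` (`length(omegas) + 1`) and `S`.
#' @export
detect_boundaries <- function(spec, n_modes_requested = 4,
                              q0 = 0.5, eps_max = NULL, W = 5) {
  if (n_modes_requested < 2) {
    stop_fbewt("`n_modes_requested` must be >= 2.", "fbewt_invalid_argument")
  }
  magnitude <- if (inherits(spec, "fbse_spectrum")) {
    abs(spec$coefficients)
  } else if (is.numeric(spec)) {
    abs(spec)
  } else {
    stop_fbewt("`spec` must be an fbse_spectrum or a numeric vector.",
               "fbewt_invalid_argument")
  }
  S <- length(magnitude)
  if (S < 2 * n_modes_requested) {
    stop_fbewt("spectrum too short for the requested number of modes.",
               "fbewt_invalid_input")
  }
  idx <- .boundaries_for_magnitude(magnitude, n_modes_requested, q0, eps_max, W)
  structure(
    list(
      omegas = pi * idx / S,
      indices = idx,
      n_modes = length(idx) + 1L,
      S = S
    ),
    class = "fbewt_boundaries"
  )
}

#' @export
print.fbewt_boundaries <- function(x, ...) {
  cat(sprintf("<fbewt_boundaries> %d boundaries (%d modes): %s\n",
              length(x$omegas), x$n_modes,
              paste(sprintf("%.3f*pi", x$omegas / pi), collapse = ", ")))
  invisible(x)
}
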