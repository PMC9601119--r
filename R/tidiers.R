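#' Tidy a cross-validated evaluation
#'
#' One row per metric with its percentage value, plus the confusion counts
#' the metrics are derived from.
#'
#' @param x A `fbewt_eval` from [crossval_evaluate()].
#' @param ... Unused.
#' @return A tibble with columns `dimension`, `metric`, `value`.
#' @export
tidy.fbewt_eval <- function(x, ...) {
  tibble::tibble(
    dimension = x$dimension,
    metric = names(x$metrics),
    value = unname(x$metrics)
  )
}

#' Glance at a cross-validated evaluation
#'
#' @param x A `fbewt_eval`.
#' @param ... Unused.
#' @return A one-row tibble: the five metric percentages, the confusion
#'   counts, `n`, `k_folds`, classifier name and `seed`.
#' @export
glance.fbewt_eval <- function(x, ...) {
  tibble::tibble(
    dimension = x$dimension,
    accuracy = x$metrics[["accuracy"]],
    sensitivity = x$metrics[["sensitivity"]],
    specificity = x$metrics[["specificity"]],
    precision = x$metrics[["precision"]],
    f1 = x$metrics[["f1"]],
    tp = x$confusion[["tp"]], tn = x$confusion[["tn"]],
    fp = x$confusion[["fp"]], fn = x$confusion[["fn"]],
    n = x$n, k_folds = x$k_folds,
    classifier = x$classifier$classifier,
    seed = x$seed
  )
}

#' Tidy a Fourier-Bessel spectrum
#'
#' @param x An `fbse_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `order`, `frequency` (Hz), `coefficient`,
#'   `magnitude` and `energy`.
#' @export
tidy.fbse_spectrum <- function(x, ...) {
  tibble::tibble(
    order = seq_len(x$S),
    frequency = x$freq_grid,
    coefficient = x$coefficients,
    magnitude = abs(x$coefficients),
    energy = energy_spectrum(x)
  )
}

#' Tidy a mode decomposition
#'
#' @param x An `fbewt_modes`.
#' @param ... Unused.
#' @return A long tibble with columns `mode` (mode1 = low-frequency
#'   component), `sample` and `value`.
#' @export
tidy.fbewt_modes <- function(x, ...) {
  m <- mode_matrix(x)
  tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(m), sample = seq_len(nrow(m))),
    -"sample", names_to = "mode", values_to = "value"
  )
}
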