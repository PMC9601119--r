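#' Plot an empirical wavelet filter bank
#'
#' Frequency responses of the scaling function and each wavelet over
#' normalised frequency, with the detected boundaries marked.
#'
#' @param object A `fbewt_bank`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fbewt_bank <- function(object, ...) {
  resp <- cbind(phi = object$phi, object$nus)
  colnames(resp) <- c("scaling", paste0("wavelet", seq_len(object$M)))
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(resp), omega = object$grid / pi),
    -"omega", names_to = "filter", values_to = "response"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$omega, .data$response,
                                   colour = .data$filter)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$omegas / pi, linetype = "dotted") +
    ggplot2::labs(x = expression(omega / pi), y = "response",
                  colour = NULL,
                  title = sprintf("Empirical wavelet bank (tau = %.3f)",
                                  object$tau)) +
    ggplot2::theme_minimal()
}

#' Plot the components of a mode decomposition
#'
#' One facet per narrow-band component, lowest band on top.
#'
#' @param object A `fbewt_modes`.
#' @param fs Optional sampling rate; when given the x axis is seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fbewt_modes <- function(object, fs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(fs)) df$sample <- (df$sample - 1) / fs
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$mode), scales = "free_y") +
    ggplot2::labs(x = if (is.null(fs)) "sample" else "time [s]", y = NULL,
                  title = "FBSE-EWT mode decomposition") +
    ggplot2::theme_minimal()
}

#' Plot a Fourier-Bessel magnitude spectrum
#'
#' @param object An `fbse_spectrum`.
#' @param ... Unused.
#' @return A ggplot of `|K(i)|` against frequency.
#' @export
autoplot.fbse_spectrum <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$frequency, .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency [Hz]", y = "|K(i)|",
                  title = "FBSE magnitude spectrum") +
    ggplot2::theme_minimal()
}

#' Plot the confusion matrix of an evaluation
#'
#' @param object A `fbewt_eval`.
#' @param ... Unused.
#' @return A ggplot tile chart of the pooled confusion counts.
#' @export
autoplot.fbewt_eval <- function(object, ...) {
  cf <- object$confusion
  df <- tibble::tibble(
    truth = c("high", "low", "low", "high"),
    predicted = c("high", "low", "high", "low"),
    count = as.integer(cf[c("tp", "tn", "fp", "fn")])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(title = sprintf("%s: accuracy %.2f%%", object$dimension,
                                  object$metrics[["accuracy"]])) +
    ggplot2::theme_minimal()
}
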