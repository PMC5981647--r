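#' Plot wide-format spectra
#'
#' Line plot of every sample column of a wide spectra tibble against
#' wavelength, one colored line per sample.
#'
#' @param spectra Wide spectra tibble (`wavelength_nm` + sample columns).
#' @return A ggplot object.
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' plot_spectra(pa_spectra(sig, mixture_singles(names(sig)[-1], 100)))
#' @export
plot_spectra <- function(spectra) {
  split_spectra(spectra) # validates
  long <- tidyr::pivot_longer(spectra, -"wavelength_nm",
                              names_to = "sample", values_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength_nm, .data$signal,
                                     color = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "signal (a.u.)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_simpls Plot the regression-coefficient spectra, one panel
#'   per component. Large |coefficient| marks wavelengths that drive the
#'   concentration estimate.
#' @param object For `autoplot.simpls`: the fitted model.
#' @export
autoplot.simpls <- function(object, ...) {
  td <- tidy(object)
  xvar <- if ("wavelength_nm" %in% names(td)) "wavelength_nm" else "term"
  if (xvar == "term") td$term <- seq_len(nrow(td)) # nocov
  ggplot2::ggplot(td, ggplot2::aes(.data[[xvar]], .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient (ppm per a.u.)") +
    ggplot2::theme_minimal()
}

#' @describeIn kfold_cross_validate Held-out predicted versus true
#'   concentrations, colored by component, with the identity line.
#' @param object For `autoplot.simpls_cv`: the cross-validation result.
#' @export
autoplot.simpls_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$true_ppm, .data$raw_ppm,
                               color = .data$component)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "true concentration (ppm)",
                  y = "held-out prediction (ppm)", color = NULL) +
    ggplot2::theme_minimal()
}
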