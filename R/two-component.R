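#' Reference predictions for three two-component validation mixtures
#'
#' Loads the packaged table of concentrations returned by a SIMPLS model
#' calibrated on measured photoacoustic spectra of six volatile organic
#' compounds, applied to three binary 2-butanone/1-propanol validation
#' mixtures (30/70, 50/50 and 70/30 ppm; the other four compounds absent).
#' The predictions are printed to integer ppm precision, so summary
#' statistics recomputed from them can differ from values derived from the
#' unrounded model output by roughly the rounding scale.
#'
#' @return A tibble with 18 rows and columns `mixture`, `component`,
#'   `true_ppm`, `predicted_ppm`.
#' @examples
#' two_component_validation()
#' @export
two_component_validation <- function() {
  path <- system.file("extdata", "two_component_validation.csv",
                      package = "photopls", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    abort("packaged two-component validation table not found.")
  }
  out <- readr::read_csv(path, col_types = readr::cols(
    mixture = readr::col_character(),
    component = readr::col_character(),
    true_ppm = readr::col_double(),
    predicted_ppm = readr::col_double()
  ))
  if (nrow(out) != 18 || anyNA(out)) {
    abort("packaged two-component validation table is corrupt.")
  }
  out
}

#' Validation metrics for the packaged two-component mixtures
#'
#' Recomputes RMSE, bias, residual standard deviation and PRESS from the
#' packaged prediction table ([two_component_validation()]), for the raw
#' predictions and for the nonnegativity-clamped variant. Because the table
#' is rounded to integer ppm, these values carry a rounding tolerance of
#' order 1% relative to statistics computed from unrounded predictions; the
#' raw-versus-clamped ordering is unaffected.
#'
#' @return A two-row tibble ([validation_summary()] layout) with an
#'   additional `note` column recording the rounding caveat.
#' @examples
#' two_component_metrics()
#' @export
two_component_metrics <- function() {
  tab <- two_component_validation()
  out <- validation_summary(tab$true_ppm, tab$predicted_ppm)
  out$note <- "recomputed from integer-rounded predictions"
  out
}
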