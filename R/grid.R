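#' Wavelength grid for spectral simulation
#'
#' Builds the ordered wavelength axis on which cross-sections and
#' photoacoustic spectra are evaluated. The default covers the mid-infrared
#' scan range of a tunable optical parametric oscillator, 3250--3550 nm, at
#' 301 evenly spaced points (1 nm step).
#'
#' @param from,to Range of the grid in nm. `from` must be smaller than `to`.
#' @param length Number of grid points (default 301).
#'
#' @return A numeric vector of strictly increasing wavelengths in nm, with
#'   class `"wavelength_grid"` retained only implicitly (it is a plain
#'   numeric vector usable anywhere a wavelength axis is expected).
#' @examples
#' grid <- wavelength_grid()
#' range(grid)
#' length(grid)
#' @export
wavelength_grid <- function(from = 3250, to = 3550, length = 301) {
  if (!is.numeric(from) || !is.numeric(to) || from >= to) {
    abort("`from` must be smaller than `to`.")
  }
  if (length < 2) {
    abort("`length` must be at least 2.")
  }
  seq(from, to, length.out = length)
}

# Validate a user-supplied wavelength axis: numeric, finite, strictly increasing.
check_wavelength_grid <- function(grid, arg = "grid") {
  if (!is.numeric(grid) || length(grid) < 2 || anyNA(grid) || any(!is.finite(grid))) {
    abort(sprintf("`%s` must be a numeric vector of at least 2 finite wavelengths.", arg))
  }
  if (any(diff(grid) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing.", arg))
  }
  invisible(grid)
}

# Pull the wavelength axis and sample columns out of a wide spectra tibble.
# Used by every function that consumes spectra in the wide CSV layout.
split_spectra <- function(spectra, arg = "spectra") {
  if (!is.data.frame(spectra) || !"wavelength_nm" %in% names(spectra)) {
    abort(sprintf("`%s` must be a data frame with a `wavelength_nm` column.", arg))
  }
  grid <- spectra[["wavelength_nm"]]
  check_wavelength_grid(grid, arg = paste0(arg, "$wavelength_nm"))
  value_cols <- setdiff(names(spectra), "wavelength_nm")
  if (length(value_cols) == 0) {
    abort(sprintf("`%s` has no sample columns besides `wavelength_nm`.", arg))
  }
  signals <- as.matrix(spectra[value_cols])
  if (!is.numeric(signals) || anyNA(signals) || any(!is.finite(signals))) {
    abort(sprintf("all sample columns of `%s` must be finite numeric values.", arg))
  }
  list(grid = grid, signals = signals, names = value_cols)
}
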