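#' Instrument model for photoacoustic simulation
#'
#' Bundles the multiplicative instrument factors of the photoacoustic signal
#' model \eqn{S(\lambda) = C \, P(\lambda) \, N_{tot} \, \sum_i c_i
#' \sigma_i(\lambda)}: the cell constant \eqn{C} (geometry, microphone
#' position and acoustic-resonance amplification lumped together), the
#' wavelength-dependent optical power curve \eqn{P(\lambda)}, the total
#' molecular density \eqn{N_{tot}}, and the relative noise level. All
#' default to 1 (flat power) since absolute units are arbitrary and the
#' calibration absorbs every multiplicative constant; a nonflat power curve
#' matters only until power normalization.
#'
#' @param cell_constant Scalar \eqn{C}, a.u.
#' @param power_curve Either a single positive number (flat power), a
#'   numeric vector with one value per grid point, or a function of
#'   wavelength in nm returning the power in a.u.
#' @param total_density Scalar \eqn{N_{tot}}, a.u.
#' @param noise_fraction Standard deviation of additive Gaussian noise as a
#'   fraction of the spectrum root mean square (default 0.10).
#'
#' @return A list of class `"instrument_model"`.
#' @export
instrument_model <- function(cell_constant = 1, power_curve = 1,
                             total_density = 1, noise_fraction = 0.10) {
  if (!is.numeric(cell_constant) || length(cell_constant) != 1) {
    abort("`cell_constant` must be a single number.")
  }
  if (!is.numeric(total_density) || length(total_density) != 1) {
    abort("`total_density` must be a single number.")
  }
  if (!is.numeric(noise_fraction) || length(noise_fraction) != 1 || noise_fraction < 0) {
    abort("`noise_fraction` must be a single nonnegative number.")
  }
  if (!is.function(power_curve) && !is.numeric(power_curve)) {
    abort("`power_curve` must be numeric or a function of wavelength.")
  }
  structure(
    list(cell_constant = cell_constant, power_curve = power_curve,
         total_density = total_density, noise_fraction = noise_fraction),
    class = "instrument_model"
  )
}

# Evaluate the instrument power curve on a grid.
power_at <- function(instrument, grid) {
  p <- instrument$power_curve
  if (is.function(p)) {
    p <- p(grid)
  } else if (length(p) == 1) {
    p <- rep(p, length(grid))
  }
  if (length(p) != length(grid)) {
    abort("`power_curve` length does not match the wavelength grid.")
  }
  p
}

#' Simulate photoacoustic mixture spectra
#'
#' Applies the linear photoacoustic forward model: the signal of an
#' N-component gas mixture is the concentration-weighted sum of the
#' component cross-sections, scaled by the instrument factors,
#' \eqn{S(\lambda) = C P(\lambda) N_{tot} \sum_i c_i \sigma_i(\lambda)},
#' with concentrations entered in ppm and converted to absolute fraction
#' internally. The output is noiseless and unnormalized; see
#' [normalize_by_power()] and [add_noise()].
#'
#' @param xsec Cross-section tibble from [cross_sections()]:
#'   `wavelength_nm` plus one column per component.
#' @param mixtures Either a named numeric vector of ppm concentrations for a
#'   single mixture, or a data frame with one row per mixture, one column
#'   per component (ppm) and an optional `sample` column of identifiers.
#'   Every named component must exist in `xsec`; concentrations must be
#'   finite and nonnegative.
#' @param instrument An [instrument_model()].
#'
#' @return A wide spectra tibble: `wavelength_nm` plus one signal column per
#'   mixture (a.u.).
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' s <- pa_spectra(sig, c(`2-butanone` = 30, `1-propanol` = 70))
#' head(s)
#' @export
pa_spectra <- function(xsec, mixtures, instrument = instrument_model()) {
  parts <- split_spectra(xsec, arg = "xsec")
  if (is.numeric(mixtures) && !is.null(names(mixtures))) {
    mixtures <- tibble::as_tibble(as.list(mixtures))
  }
  if (!is.data.frame(mixtures) || nrow(mixtures) == 0) {
    abort("`mixtures` must be a named vector or a data frame of ppm concentrations.")
  }
  sample_ids <- if ("sample" %in% names(mixtures)) {
    as.character(mixtures$sample)
  } else {
    paste0("mix_", seq_len(nrow(mixtures)))
  }
  conc_cols <- setdiff(names(mixtures), "sample")
  unknown <- setdiff(conc_cols, parts$names)
  if (length(unknown)) {
    abort(paste0("no cross-section model for component(s): ",
                 paste(unknown, collapse = ", ")))
  }
  conc <- as.matrix(mixtures[conc_cols])
  if (anyNA(conc) || any(!is.finite(conc))) abort("concentrations must be finite.")
  if (any(conc < 0)) abort("concentrations must be nonnegative (ppm).")

  scale <- instrument$cell_constant * instrument$total_density *
    power_at(instrument, parts$grid)
  # signals: wavelengths x mixtures; ppm -> absolute molar fraction
  sigma <- parts$signals[, conc_cols, drop = FALSE]
  signal <- (sigma %*% t(conc * 1e-6)) * scale
  out <- tibble::tibble(wavelength_nm = parts$grid)
  out[sample_ids] <- as.data.frame(signal)
  out
}

#' Power-normalize photoacoustic spectra
#'
#' Divides each spectrum by the optical power curve at every wavelength,
#' mirroring the standard practice of normalizing the (power-proportional)
#' photoacoustic signal by the averaged emitted power so that spectra taken
#' with a wavelength-dependent source become comparable. The composition
#' with [pa_spectra()] is independent of the power curve.
#'
#' @param spectra Wide spectra tibble (`wavelength_nm` + sample columns).
#' @param instrument An [instrument_model()]; its power curve must be
#'   strictly positive at every grid point.
#'
#' @return The normalized spectra tibble.
#' @export
normalize_by_power <- function(spectra, instrument = instrument_model()) {
  parts <- split_spectra(spectra)
  p <- power_at(instrument, parts$grid)
  if (any(p <= 0)) {
    abort("power curve must be strictly positive at every grid point.")
  }
  out <- spectra
  out[parts$names] <- as.data.frame(parts$signals / p)
  out
}

#' Add Gaussian noise scaled to the spectrum RMS
#'
#' Adds i.i.d. zero-mean Gaussian noise to every sample column, with
#' standard deviation equal to `noise_fraction` times that spectrum's root
#' mean square. This reproduces a noise power equal to a stated fraction of
#' the spectrum power when power is measured as the RMS over all points.
#' Negative signal values are kept (microphone readings can dip below
#' baseline); nothing is floored.
#'
#' @param spectra Wide spectra tibble.
#' @param noise_fraction Nonnegative noise-to-signal RMS ratio (default 0.10).
#' @param seed Integer seed for reproducibility; `NULL` uses the current RNG
#'   stream.
#'
#' @return The noisy spectra tibble.
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' s <- pa_spectra(sig, c(`2-butanone` = 100))
#' noisy <- add_noise(s, 0.10, seed = 7)
#' @export
add_noise <- function(spectra, noise_fraction = 0.10, seed = NULL) {
  if (!is.numeric(noise_fraction) || length(noise_fraction) != 1 || noise_fraction < 0) {
    abort("`noise_fraction` must be a single nonnegative number.")
  }
  parts <- split_spectra(spectra)
  if (noise_fraction == 0) {
    return(spectra)
  }
  sig <- parts$signals
  noisy <- with_seed_restore(seed, {
    rms <- sqrt(colMeans(sig^2))
    sig + sweep(matrix(rnorm(length(sig)), nrow(sig)), 2,
                noise_fraction * rms, "*")
  })
  out <- spectra
  out[parts$names] <- as.data.frame(noisy)
  out
}

#' Liquid volume for preparing a ppm-level gas standard
#'
#' Computes the liquid volume of a volatile organic compound that must be
#' evaporated inside a nitrogen-filled sampling bag to reach a target molar
#' concentration: \eqn{V_{VOC} = V_{N_2} \, c_{VOC} \, M_{VOC} / (V_{ideal}
#' \, \rho_{VOC})}, with the ppm concentration converted to an absolute
#' fraction.
#'
#' @param v_n2_l Nitrogen (bag) volume in liters at normal pressure.
#' @param c_voc_ppm Target concentration in ppm.
#' @param molar_mass Molar mass of the compound, g/mol.
#' @param liquid_density Density of the liquid compound, g/mL.
#' @param v_ideal_l_mol Molar volume of an ideal gas, L/mol; default 22.414
#'   (0 degrees C, 1 atm), overridable for other temperature conventions.
#'
#' @return Required liquid volume in mL.
#' @examples
#' # 100 ppm 2-butanone in a 10 L bag
#' required_liquid_volume(10, 100, molar_mass = 72.11, liquid_density = 0.805)
#' @export
required_liquid_volume <- function(v_n2_l, c_voc_ppm, molar_mass,
                                   liquid_density, v_ideal_l_mol = 22.414) {
  if (v_n2_l <= 0) abort("`v_n2_l` must be positive.")
  if (c_voc_ppm < 0) abort("`c_voc_ppm` must be nonnegative.")
  if (molar_mass <= 0) abort("`molar_mass` must be positive.")
  if (liquid_density <= 0) abort("`liquid_density` must be positive.")
  if (v_ideal_l_mol <= 0) abort("`v_ideal_l_mol` must be positive.")
  # L * (mol/L) * (g/mol) / (g/mL) = mL
  v_n2_l * (c_voc_ppm * 1e-6) * molar_mass / (v_ideal_l_mol * liquid_density)
}

#' Physical properties of the six example volatile organic compounds
#'
#' Molar masses and liquid densities (at room temperature) for the six
#' breath-biomarker candidates used throughout the package examples,
#' sufficient for [required_liquid_volume()].
#'
#' @return A tibble with columns `component`, `molar_mass` (g/mol) and
#'   `liquid_density` (g/mL).
#' @export
voc_properties <- function() {
  tibble::tribble(
    ~component,     ~molar_mass, ~liquid_density,
    "2-butanone",   72.11,       0.805,
    "1-propanol",   60.10,       0.803,
    "isoprene",     68.12,       0.681,
    "ethylbenzene", 106.17,      0.867,
    "styrene",      104.15,      0.906,
    "hexanal",      100.16,      0.815
  )
}
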