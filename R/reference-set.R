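#' Full-factorial concentration design
#'
#' Enumerates every combination of scale factors across components and
#' converts it to ppm via the base concentration. With the defaults (factors
#' 0, 0.3, 0.7, 1 and 100 ppm base) each component takes the levels 0, 30,
#' 70 and 100 ppm, and six components give \eqn{4^6 = 4096} unique rows.
#' Rows are ordered lexicographically with the last component varying
#' fastest, so the first row is all zeros and the last is all at base
#' concentration.
#'
#' @param components Character vector of component names (defines column
#'   order), or a single count (columns are then named `comp_1`, ...).
#' @param scale_factors Distinct dimensionless factors, each in \[0, 1\].
#' @param base_concentration Concentration corresponding to factor 1, ppm.
#'
#' @return A tibble of ppm concentrations, one column per component,
#'   `length(scale_factors)^n` rows.
#' @examples
#' concentration_grid(2)
#' nrow(concentration_grid(6)) # 4096
#' @export
concentration_grid <- function(components,
                               scale_factors = c(0, 0.3, 0.7, 1),
                               base_concentration = 100) {
  if (is.numeric(components) && length(components) == 1) {
    components <- paste0("comp_", seq_len(components))
  }
  n <- length(components)
  if (n < 1) abort("need at least one component.")
  check_scale_factors(scale_factors)
  if (base_concentration <= 0) abort("`base_concentration` must be positive.")
  # expand.grid varies its first argument fastest; feed components in
  # reverse so the LAST component varies fastest, then restore column order.
  g <- expand.grid(rev(replicate(n, scale_factors, simplify = FALSE)),
                   KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g)[, n:1, drop = FALSE]
  colnames(g) <- components
  tibble::as_tibble(g * base_concentration)
}

check_scale_factors <- function(scale_factors) {
  if (!is.numeric(scale_factors) || length(scale_factors) < 1 ||
      anyNA(scale_factors) || anyDuplicated(scale_factors)) {
    abort("`scale_factors` must be distinct finite numbers.")
  }
  if (any(scale_factors < 0 | scale_factors > 1)) {
    abort("`scale_factors` must lie in [0, 1].")
  }
  invisible(scale_factors)
}

#' Build a factorial calibration reference set
#'
#' Constructs the calibration corpus for multivariate calibration from one
#' measured (or simulated) single-component spectrum per component, all at a
#' common base concentration: every spectrum is scaled by each factor and
#' the scaled spectra are added to one another in all possible combinations.
#' The row for factor tuple \eqn{(f_1, \dots, f_N)} has predictor
#' \eqn{x = \sum_i f_i s_i} (plus noise) and response
#' \eqn{y = (f_1, \dots, f_N) \cdot} base concentration in ppm. The
#' factor-1 rows reproduce the originals; nothing is appended separately.
#'
#' Two noise protocols are available. `"per_reference"` (default) adds
#' independent Gaussian noise to every generated row, the standard
#' augmentation reading, which keeps the noise subspace full-rank.
#' `"originals"` perturbs only the N single-component spectra once, before
#' combination, so rows built from the same original share exactly
#' correlated noise contributions. Noise standard deviation is
#' `noise_fraction` times the RMS of the spectrum it is added to.
#'
#' @param singles Wide spectra tibble with one column per component, each
#'   the single-component spectrum at `base_concentration`.
#' @param scale_factors Distinct factors in \[0, 1\]; default `c(0, 0.3, 0.7, 1)`.
#' @param base_concentration Concentration of the single spectra, ppm.
#' @param noise_fraction Noise-to-RMS ratio; 0 gives a noiseless set.
#' @param noise_placement `"per_reference"` or `"originals"`, see Details.
#' @param seed Integer seed controlling the noise draw.
#'
#' @return An object of class `"reference_set"`: a list with `x` (matrix,
#'   samples x wavelengths), `y` (matrix, samples x components, ppm),
#'   `components`, `wavelength_nm`, and `config` (factors, base
#'   concentration, noise settings, seed, row-ordering note).
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
#' ref <- build_reference_set(singles, noise_fraction = 0)
#' dim(ref$x)
#' @export
build_reference_set <- function(singles,
                                scale_factors = c(0, 0.3, 0.7, 1),
                                base_concentration = 100,
                                noise_fraction = 0.10,
                                noise_placement = c("per_reference", "originals"),
                                seed = 1) {
  parts <- split_spectra(singles, arg = "singles")
  check_scale_factors(scale_factors)
  noise_placement <- match.arg(noise_placement)
  if (!is.numeric(noise_fraction) || noise_fraction < 0) {
    abort("`noise_fraction` must be nonnegative.")
  }
  components <- parts$names
  s <- parts$signals # wavelengths x components

  if (noise_placement == "originals" && noise_fraction > 0) {
    noisy <- add_noise(singles, noise_fraction, seed = seed)
    s <- split_spectra(noisy)$signals
  }

  y <- concentration_grid(components, scale_factors, base_concentration)
  f <- as.matrix(y) / base_concentration
  x <- f %*% t(s) # rows: factor combinations, cols: wavelengths

  if (noise_placement == "per_reference" && noise_fraction > 0) {
    x <- with_seed_restore(seed, {
      rms <- sqrt(rowMeans(x^2))
      x + matrix(rnorm(length(x)), nrow(x)) * (noise_fraction * rms)
    })
  }
  colnames(x) <- sprintf("wl_%g", parts$grid)

  structure(
    list(
      x = x,
      y = as.matrix(y),
      components = components,
      wavelength_nm = parts$grid,
      config = list(
        scale_factors = scale_factors,
        base_concentration = base_concentration,
        noise_fraction = noise_fraction,
        noise_placement = noise_placement,
        seed = seed,
        row_order = "lexicographic, last component varying fastest"
      )
    ),
    class = "reference_set"
  )
}

#' Single-component mixture table
#'
#' Convenience constructor for the diagonal design used to simulate one
#' spectrum per component: row i has `ppm` for component i and 0 elsewhere.
#'
#' @param components Character vector of component names.
#' @param ppm Concentration given to each component in its own row.
#' @return A tibble with a `sample` column (the component names) and one ppm
#'   column per component.
#' @export
mixture_singles <- function(components, ppm = 100) {
  m <- diag(ppm, length(components))
  colnames(m) <- components
  out <- tibble::as_tibble(m)
  out <- dplyr::mutate(out, sample = components, .before = 1)
  out
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "<reference_set> %d spectra x %d wavelengths, %d components\n",
    nrow(x$x), ncol(x$x), length(x$components)
  ))
  cat(" components:", paste(x$components, collapse = ", "), "\n")
  cat(sprintf(
    " factors {%s} x %g ppm, noise %g (%s), seed %s\n",
    paste(x$config$scale_factors, collapse = ", "),
    x$config$base_concentration, x$config$noise_fraction,
    x$config$noise_placement, format(x$config$seed)
  ))
  invisible(x)
}

#' Tidy a reference set into a long tibble
#'
#' @param x A [build_reference_set()] result.
#' @param ... Unused.
#' @return A tibble with columns `row`, `wavelength_nm`, `signal`, suitable
#'   for plotting, plus the concentrations joined by `row` via
#'   `attr(result, "concentrations")`.
#' @export
tidy.reference_set <- function(x, ...) {
  out <- tibble::tibble(
    row = rep(seq_len(nrow(x$x)), times = ncol(x$x)),
    wavelength_nm = rep(x$wavelength_nm, each = nrow(x$x)),
    signal = as.vector(x$x)
  )
  attr(out, "concentrations") <- tibble::as_tibble(x$y)
  out
}
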