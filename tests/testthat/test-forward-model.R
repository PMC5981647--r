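test_that("photoacoustic signal is linear in concentration", {
  sig <- cross_sections(make_test_library(), make_test_grid())

  # zero concentrations give the zero spectrum
  zero <- pa_spectra(sig, c(a = 0, b = 0, c = 0))
  expect_equal(zero$mix_1, rep(0, nrow(sig)))

  # scale equivariance: doubling every concentration doubles the signal
  mix <- c(a = 30, b = 70, c = 10)
  s1 <- pa_spectra(sig, mix)
  s2 <- pa_spectra(sig, 2 * mix)
  expect_equal(s2$mix_1, 2 * s1$mix_1)

  # the mixture spectrum is the pointwise sum of single-component spectra
  singles <- pa_spectra(sig, mixture_singles(c("a", "b", "c"), 1))
  expect_equal(s1$mix_1, 30 * singles$a + 70 * singles$b + 10 * singles$c,
               tolerance = 1e-12)
})

test_that("signal honours the instrument factors and the ppm conversion", {
  grid <- make_test_grid()
  sig <- cross_sections(xsection_library("a", 3400, 60, 1, baseline = 0), grid)
  inst <- instrument_model(cell_constant = 2, total_density = 3,
                           power_curve = function(l) 1 + (l - 3250) / 300)
  s <- pa_spectra(sig, c(a = 50), instrument = inst)
  expect_equal(s$mix_1,
               2 * 3 * (1 + (grid - 3250) / 300) * 50e-6 * sig$a,
               tolerance = 1e-14)
})

test_that("a mixture component without a cross-section model is a named error", {
  sig <- cross_sections(make_test_library(), make_test_grid())
  expect_error(pa_spectra(sig, c(a = 10, xylene = 5)), "xylene")
  expect_error(pa_spectra(sig, c(a = -1)), "nonnegative")
})

test_that("power normalization divides pointwise and cancels the power curve", {
  sig <- cross_sections(make_test_library(), make_test_grid())
  s <- pa_spectra(sig, c(a = 40, b = 20, c = 80))

  expect_equal(normalize_by_power(s, instrument_model()), s)
  halved <- normalize_by_power(s, instrument_model(power_curve = 2))
  expect_equal(halved$mix_1, s$mix_1 / 2)

  # normalize . simulate is independent of a nonflat power curve
  pc <- function(l) 0.5 + ((l - 3250) / 300)^2
  inst <- instrument_model(power_curve = pc)
  via_power <- normalize_by_power(pa_spectra(sig, c(a = 40, b = 20, c = 80),
                                             instrument = inst), inst)
  expect_equal(via_power$mix_1, s$mix_1, tolerance = 1e-12)

  bad <- instrument_model(power_curve = function(l) ifelse(l > 3400, 1, 0))
  expect_error(normalize_by_power(s, bad), "strictly positive")
})

test_that("noise is reproducible, optional, and scaled to the spectrum RMS", {
  s <- make_test_singles()[c("wavelength_nm", "a")]

  expect_equal(add_noise(s, 0, seed = 1), s)
  expect_identical(add_noise(s, 0.1, seed = 7), add_noise(s, 0.1, seed = 7))
  expect_false(identical(add_noise(s, 0.1, seed = 7), add_noise(s, 0.1, seed = 8)))
  expect_error(add_noise(s, -0.1), "nonnegative")

  # Monte-Carlo check of the noise contract: over 10^4 draws the RMS of
  # (noisy - clean) matches 0.10 x RMS(clean) within 2%
  n_draws <- 10000
  wide <- tibble::as_tibble(matrix(s$a, nrow(s), n_draws,
                                   dimnames = list(NULL, paste0("d", 1:n_draws))))
  wide <- dplyr::bind_cols(tibble::tibble(wavelength_nm = s$wavelength_nm), wide)
  noisy <- add_noise(wide, 0.10, seed = 123)
  resid <- as.matrix(noisy[-1]) - matrix(s$a, nrow(s), n_draws)
  target <- 0.10 * sqrt(mean(s$a^2))
  expect_equal(sqrt(mean(resid^2)), target, tolerance = 0.02)
})

test_that("negative noisy signal values are kept, not floored", {
  s <- tibble::tibble(wavelength_nm = make_test_grid(),
                      a = rep(0.001, 41))
  noisy <- add_noise(s, 5, seed = 3) # huge noise to force sign flips
  expect_true(any(noisy$a < 0))
})

test_that("liquid volume for gas-standard preparation follows the ideal-gas formula", {
  # 10 L bag, 100 ppm 2-butanone: ~4.0e-3 mL of liquid
  v <- required_liquid_volume(10, 100, molar_mass = 72.11,
                              liquid_density = 0.805)
  expect_equal(v, 10 * 100e-6 * 72.11 / (22.414 * 0.805), tolerance = 1e-12)
  expect_equal(v, 4.00e-3, tolerance = 0.002)

  expect_equal(required_liquid_volume(10, 0, 72.11, 0.805), 0)
  expect_equal(required_liquid_volume(20, 100, 72.11, 0.805), 2 * v)
  expect_error(required_liquid_volume(10, 100, 72.11, 0), "liquid_density")
  expect_error(required_liquid_volume(10, 100, 72.11, 0.805, v_ideal_l_mol = -1),
               "v_ideal")

  # properties table covers all six example compounds
  props <- voc_properties()
  expect_equal(nrow(props), 6)
  expect_true(all(props$molar_mass > 0 & props$liquid_density > 0))
})
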