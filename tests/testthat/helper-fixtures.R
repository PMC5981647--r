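# Small deterministic fixtures built in code.

# A compact 3-component band library on a coarse grid: fast enough for
# exhaustive factorial/CV tests while keeping the overlapping-band geometry.
make_test_library <- function() {
  xsection_library(
    component = c("a", "a", "b", "b", "c"),
    center_nm = c(3300, 3450, 3350, 3500, 3400),
    fwhm_nm = c(60, 40, 50, 45, 80),
    amplitude = c(1000, 600, 800, 900, 1200),
    profile = c("gaussian", "lorentzian", "gaussian", "gaussian", "lorentzian"),
    baseline = c(20, 20, 10, 10, 30)
  )
}

make_test_grid <- function(length = 41) {
  wavelength_grid(3250, 3550, length = length)
}

# Raw predictions as a samples x components matrix, via the public tidy API.
predict_mat <- function(fit, x) {
  pr <- predict(fit, x)
  n <- length(unique(pr$sample))
  matrix(pr$raw_ppm, nrow = n,
         dimnames = list(unique(pr$sample), unique(pr$component)))
}

# Single-component spectra of the test library at `ppm`.
make_test_singles <- function(ppm = 100, length = 41) {
  sig <- cross_sections(make_test_library(), make_test_grid(length))
  pa_spectra(sig, mixture_singles(names(sig)[-1], ppm))
}
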