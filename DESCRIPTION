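Package: photopls
Title: Multivariate Calibration of Overlapping Photoacoustic Gas Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining per-component gas concentrations from
    strongly overlapping mid-infrared photoacoustic absorption spectra.
    Implements a linear photoacoustic mixture forward model with a
    configurable instrument (cell constant, optical power curve, Gaussian
    noise scaled to the spectrum root mean square), full-factorial synthesis
    of calibration reference sets from single-component spectra, a
    from-scratch SIMPLS partial least squares regression with broom-style
    accessors, and validation statistics (RMSEC, PRESS, bias, standard
    deviation, k-fold cross-validation, non-negativity clamping). Includes a
    packaged worked example of six volatile organic compounds quantified in
    two-component validation mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
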