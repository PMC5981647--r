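#' Read and write wide-format spectra CSV
#'
#' The on-disk spectra layout is one UTF-8 CSV with a header row: first
#' column `wavelength_nm`, then one column per sample, '.' as decimal
#' separator. Wavelengths must be strictly increasing; duplicated or
#' unsorted wavelengths and non-numeric cells are rejected with the
#' offending data line number. Values survive a write-read round trip to at
#' least 12 significant digits.
#'
#' @param path File path.
#' @param spectra Wide spectra tibble (`wavelength_nm` + sample columns).
#' @return `read_spectra_csv()` returns the spectra tibble;
#'   `write_spectra_csv()` returns `path` invisibly.
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  out <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed cell in %s at line %d: expected a number.",
                  path, probs$row[1]))
  }
  if (names(out)[1] != "wavelength_nm") {
    abort("first column must be `wavelength_nm`.")
  }
  if (ncol(out) < 2) abort("no sample columns found.")
  wl <- out$wavelength_nm
  if (anyNA(out)) {
    bad <- which(!stats::complete.cases(out))[1]
    abort(sprintf("missing value in %s at line %d.", path, bad + 1L))
  }
  bad <- which(diff(wl) <= 0)
  if (length(bad)) {
    what <- if (wl[bad[1] + 1] == wl[bad[1]]) "duplicated" else "unsorted"
    abort(sprintf("%s wavelength in %s at line %d.", what, path, bad[1] + 2L))
  }
  out
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(spectra, path) {
  split_spectra(spectra) # validates
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Persist and restore a reference set
#'
#' A reference set is stored as a directory of plain-text artifacts:
#' `x.csv` (one row per reference spectrum, first column `sample`),
#' `y.csv` (matching ppm concentrations, component-name header) and
#' `meta.json` (wavelength grid, configuration, seed and the row-ordering
#' convention), so any stored corpus carries what is needed to regenerate
#' it.
#'
#' @param ref A [build_reference_set()] object.
#' @param dir Directory to create/use.
#' @return `write_reference_set()` returns `dir` invisibly;
#'   `read_reference_set()` returns the restored `reference_set`.
#' @export
write_reference_set <- function(ref, dir) {
  stopifnot(inherits(ref, "reference_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_id <- seq_len(nrow(ref$x))
  x_tbl <- tibble::as_tibble(ref$x)
  x_tbl <- dplyr::mutate(x_tbl, sample = sample_id, .before = 1)
  y_tbl <- tibble::as_tibble(ref$y)
  y_tbl <- dplyr::mutate(y_tbl, sample = sample_id, .before = 1)
  readr::write_csv(x_tbl, file.path(dir, "x.csv"), progress = FALSE)
  readr::write_csv(y_tbl, file.path(dir, "y.csv"), progress = FALSE)
  meta <- list(
    format_version = 1L,
    components = ref$components,
    wavelength_nm = ref$wavelength_nm,
    config = ref$config
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(dir) {
  paths <- file.path(dir, c("x.csv", "y.csv", "meta.json"))
  if (!all(file.exists(paths))) {
    abort(sprintf("`%s` is not a stored reference set (x.csv/y.csv/meta.json).", dir))
  }
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  x <- as.matrix(readr::read_csv(paths[1], col_types = readr::cols(),
                                 progress = FALSE)[, -1])
  y <- as.matrix(readr::read_csv(paths[2], col_types = readr::cols(),
                                 progress = FALSE)[, -1])
  structure(
    list(
      x = x,
      y = y,
      components = meta$components,
      wavelength_nm = meta$wavelength_nm,
      config = meta$config
    ),
    class = "reference_set"
  )
}

matrix_to_json <- function(m) {
  list(dim = dim(m), order = "row-major", values = as.vector(t(m)))
}

matrix_from_json <- function(j) {
  matrix(j$values, nrow = j$dim[1], ncol = j$dim[2], byrow = TRUE)
}

#' Serialize a fitted SIMPLS model to JSON
#'
#' Writes every matrix of the fitted model (row-major, with explicit
#' dimensions), the centering vectors, variance-explained fractions,
#' component names and wavelength grid into a versioned JSON container at
#' full double precision. [read_simpls()] restores a model whose
#' predictions match the original bit-for-bit at the stored precision.
#'
#' @param model A [fit_simpls()] object.
#' @param path Output/input JSON file path.
#' @return `write_simpls()` returns `path` invisibly; `read_simpls()`
#'   returns the restored `"simpls"` model.
#' @export
write_simpls <- function(model, path) {
  stopifnot(inherits(model, "simpls"))
  payload <- list(
    format_version = 1L,
    n_factors = model$n_factors,
    n_samples = model$n_samples,
    scaled = model$scaled,
    components = model$components,
    wavelengths = model$wavelengths,
    x_mean = as.numeric(model$x_mean),
    y_mean = as.numeric(model$y_mean),
    x_scale = model$x_scale,
    weights = matrix_to_json(model$weights),
    scores = matrix_to_json(model$scores),
    x_loadings = matrix_to_json(model$x_loadings),
    y_loadings = matrix_to_json(model$y_loadings),
    coefficients = matrix_to_json(model$coefficients),
    x_variance_explained = model$x_variance_explained,
    y_variance_explained = model$y_variance_explained,
    predictor_names = rownames(model$coefficients)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_simpls
#' @export
read_simpls <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$format_version) || j$format_version != 1L) {
    abort("unsupported model file version.")
  }
  b <- matrix_from_json(j$coefficients)
  dimnames(b) <- list(j$predictor_names, j$components)
  structure(
    list(
      x_mean = setNames(j$x_mean, j$predictor_names),
      y_mean = setNames(j$y_mean, j$components),
      x_scale = j$x_scale,
      scaled = isTRUE(j$scaled),
      n_factors = j$n_factors,
      n_samples = j$n_samples,
      weights = matrix_from_json(j$weights),
      scores = matrix_from_json(j$scores),
      x_loadings = matrix_from_json(j$x_loadings),
      y_loadings = matrix_from_json(j$y_loadings),
      coefficients = b,
      x_variance_explained = j$x_variance_explained,
      y_variance_explained = j$y_variance_explained,
      components = j$components,
      wavelengths = j$wavelengths
    ),
    class = "simpls"
  )
}

#' Read and write a component band library file
#'
#' A component library file lists, per component, its band parameters
#' (center, width, amplitude, profile) and baseline, in JSON or YAML:
#'
#' ```yaml
#' components:
#'   acetone:
#'     baseline: 0.5
#'     bands:
#'       - {center_nm: 3380, fwhm_nm: 40, amplitude: 1.2, profile: gaussian}
#' ```
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @param library An [xsection_library()] tibble.
#' @return `read_xsection_library()` returns an [xsection_library()];
#'   `write_xsection_library()` returns `path` invisibly.
#' @export
read_xsection_library <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort("component library must be a .yaml/.yml or .json file.")
  }
  if (!is.list(spec$components) || length(spec$components) == 0) {
    abort("component library file must contain a nonempty `components` mapping.")
  }
  rows <- purrr::imap(spec$components, function(comp, name) {
    bands <- purrr::map(comp$bands, function(b) {
      tibble::tibble(
        component = name,
        center_nm = as.numeric(b$center_nm),
        fwhm_nm = as.numeric(b$fwhm_nm),
        amplitude = as.numeric(b$amplitude),
        profile = b$profile %||% "gaussian",
        baseline = as.numeric(comp$baseline %||% 0)
      )
    })
    dplyr::bind_rows(bands)
  })
  lib <- dplyr::bind_rows(rows)
  validate_xsection_library(lib)
  class(lib) <- c("xsection_library", class(tibble::tibble()))
  lib
}

#' @rdname read_xsection_library
#' @export
write_xsection_library <- function(library, path) {
  validate_xsection_library(library)
  comps <- lapply(split(library, library$component), function(rows) {
    list(
      baseline = rows$baseline[1],
      bands = lapply(seq_len(nrow(rows)), function(i) {
        list(center_nm = rows$center_nm[i], fwhm_nm = rows$fwhm_nm[i],
             amplitude = rows$amplitude[i], profile = rows$profile[i])
      })
    )
  })
  payload <- list(components = comps[unique(library$component)])
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' Reads a YAML or JSON configuration describing a full calibration run.
#' Recognized top-level keys: `grid` (`from`, `to`, `length`), `library`
#' (path to a band-parameter file or `"default"`), `instrument`,
#' `augmentation` (`scale_factors`, `base_concentration`, `noise_fraction`,
#' `noise_placement`), `pls` (`n_factors`, `scale`), `cv` (`k`), `output`,
#' and `seed`. Unknown keys are rejected with a message naming them, so a
#' typo cannot silently fall back to a default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list with defaults filled in for absent keys.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("configuration must be a .yaml/.yml or .json file.")
  }
  if (!is.list(cfg)) abort("configuration must be a mapping of sections.")
  known <- c("grid", "library", "instrument", "augmentation", "pls", "cv",
             "output", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", "),
                 ". Known keys: ", paste(known, collapse = ", "), "."))
  }
  defaults <- list(
    grid = list(from = 3250, to = 3550, length = 301L),
    library = "default",
    instrument = list(cell_constant = 1, power_curve = 1, total_density = 1,
                      noise_fraction = 0.10),
    augmentation = list(scale_factors = c(0, 0.3, 0.7, 1),
                        base_concentration = 100, noise_fraction = 0.10,
                        noise_placement = "per_reference"),
    pls = list(n_factors = 6L, scale = FALSE),
    cv = list(k = 10L),
    output = NULL,
    seed = 1L
  )
  utils::modifyList(defaults, cfg)
}
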