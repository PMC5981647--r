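#' k-fold cross-validation of a SIMPLS calibration
#'
#' Shuffles the reference rows with a seeded RNG, partitions them into `k`
#' near-equal folds, fits the model on all-but-one fold and predicts the
#' held-out fold, then pools every held-out prediction into a single
#' validation summary. Fold assignment is reproducible per seed; folds are
#' disjoint and cover every row exactly once. No stratification is applied.
#'
#' @param ref A [build_reference_set()] object.
#' @param k Number of folds (default 10); between 2 and the number of rows.
#' @param n_factors PLS factors per fold model (default 6).
#' @param seed Integer seed for the fold shuffle.
#'
#' @return An object of class `"simpls_cv"`: list with `predictions` (tibble
#'   of `row`, `fold`, `component`, `true_ppm`, `raw_ppm`, `clamped_ppm`),
#'   `summary` (raw and clamped [validation_summary()] rows; the raw
#'   `std_ppm` is the pooled held-out standard deviation and `rmse_ppm` the
#'   RMSECV), `folds` (integer assignment per row), `k`, `n_factors`,
#'   `seed`.
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
#' ref <- build_reference_set(singles, scale_factors = c(0, 1),
#'                            noise_fraction = 0.1, seed = 2)
#' cv <- kfold_cross_validate(ref, k = 4, n_factors = 6, seed = 3)
#' cv$summary
#' @export
kfold_cross_validate <- function(ref, k = 10, n_factors = 6, seed = 1) {
  stopifnot(inherits(ref, "reference_set"))
  n <- nrow(ref$x)
  if (k < 2 || k > n) abort("`k` must be between 2 and the number of rows.")
  folds <- with_seed_restore(seed, {
    sample(rep_len(seq_len(k), n))
  })
  if (min(tabulate(folds, k)) == 0) abort("empty fold; reduce `k`.") # nocov
  if (n - max(tabulate(folds, k)) <= n_factors) {
    abort("training remainder smaller than `n_factors` + 1; reduce `k` or `n_factors`.")
  }

  raw <- matrix(NA_real_, n, length(ref$components),
                dimnames = list(NULL, ref$components))
  for (fold in seq_len(k)) {
    hold <- folds == fold
    fit <- fit_simpls(ref$x[!hold, , drop = FALSE],
                      ref$y[!hold, , drop = FALSE],
                      n_factors = n_factors)
    raw[hold, ] <- predict_raw(fit, ref$x[hold, , drop = FALSE])
  }

  predictions <- tibble::tibble(
    row = rep(seq_len(n), times = ncol(raw)),
    fold = rep(folds, times = ncol(raw)),
    component = rep(colnames(raw), each = n),
    true_ppm = as.vector(ref$y),
    raw_ppm = as.vector(raw),
    clamped_ppm = pmax(as.vector(raw), 0)
  )

  structure(
    list(
      predictions = predictions,
      summary = validation_summary(ref$y, raw),
      folds = folds,
      k = k,
      n_factors = n_factors,
      seed = seed
    ),
    class = "simpls_cv"
  )
}

#' @export
print.simpls_cv <- function(x, ...) {
  cat(sprintf("<simpls_cv> %d-fold, %d factors, seed %s\n",
              x$k, x$n_factors, format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @describeIn kfold_cross_validate Pooled held-out predictions, one row per
#'   sample and component.
#' @param x,... For the broom methods: the `simpls_cv` object, unused args.
#' @export
tidy.simpls_cv <- function(x, ...) x$predictions

#' @describeIn kfold_cross_validate The raw/clamped validation summary.
#' @export
glance.simpls_cv <- function(x, ...) x$summary
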