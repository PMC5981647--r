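#' Fit a SIMPLS partial least squares regression
#'
#' From-scratch implementation of the SIMPLS algorithm (de Jong 1993),
#' the direct PLS variant that computes each weight vector from the deflated
#' cross-product matrix \eqn{S = X_c^\top Y_c} rather than by deflating the
#' data matrices. Both `x` and `y` are column-mean-centered; no
#' unit-variance scaling is applied by default (matching the common
#' chemometrics default for spectra in comparable units). Per factor, the
#' weight vector is the dominant left singular vector of the current
#' cross-product; the x-scores are orthonormalized; the cross-product is
#' deflated against an orthonormal basis of the x-loadings using
#' Gram--Schmidt with re-orthogonalization. The accumulated
#' regression-coefficient matrix \eqn{B} predicts via
#' \eqn{\hat y = \bar y + (x - \bar x) B}.
#'
#' The fit is fully deterministic: the singular-vector sign ambiguity is
#' fixed by making each weight vector's largest-magnitude entry positive.
#' If the residual cross-product vanishes before `n_factors` components are
#' extracted (e.g. `y` already fully explained), fitting stops early with a
#' warning and the model records the achieved factor count.
#'
#' @param x Predictor matrix or data frame, samples x wavelengths, or a
#'   [build_reference_set()] object (in which case `y` is taken from it).
#' @param y Response matrix or data frame, samples x components (ppm).
#'   A vector is treated as a single-column matrix.
#' @param n_factors Number of PLS factors to extract (default 6). Must be
#'   at most `min(nrow(x) - 1, ncol(x))`, and `nrow(x)` must exceed
#'   `n_factors` so the model is determined.
#' @param scale If `TRUE`, also scale predictor columns to unit variance
#'   before fitting (off by default).
#'
#' @return An object of class `"simpls"`: list with centering vectors
#'   `x_mean`, `y_mean`, matrices `weights` (wavelengths x factors),
#'   `scores`, `x_loadings`, `y_loadings`, `coefficients` (wavelengths x
#'   components, ppm per a.u.), per-factor `x_variance_explained` and
#'   `y_variance_explained` fractions, `n_factors` (achieved), and dimension
#'   names.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems 18, 251--263.
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
#' ref <- build_reference_set(singles, noise_fraction = 0)
#' fit <- fit_simpls(ref, n_factors = 6)
#' glance(fit)
#' @export
fit_simpls <- function(x, y = NULL, n_factors = 6, scale = FALSE) {
  if (inherits(x, "reference_set")) {
    y <- x$y
    wavelengths <- x$wavelength_nm
    x <- x$x
  } else {
    wavelengths <- NULL
  }
  x <- as.matrix(x)
  if (is.null(y)) abort("`y` is required when `x` is not a reference set.")
  y <- as.matrix(y)
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric.")
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same number of rows.")
  n <- nrow(x)
  p <- ncol(x)
  m <- ncol(y)
  if (n_factors < 1) abort("`n_factors` must be at least 1.")
  if (n <= n_factors) {
    abort("the number of samples must exceed `n_factors`.")
  }
  if (n_factors > min(n - 1, p)) {
    abort("`n_factors` must be at most min(nrow(x) - 1, ncol(x)).")
  }

  x_mean <- colMeans(x)
  y_mean <- colMeans(y)
  xc <- sweep(x, 2, x_mean)
  yc <- sweep(y, 2, y_mean)
  x_scale <- rep(1, p)
  if (isTRUE(scale)) {
    x_scale <- apply(xc, 2, stats::sd)
    if (any(x_scale == 0)) abort("cannot scale: zero-variance predictor column.")
    xc <- sweep(xc, 2, x_scale, "/")
  }
  ss_x <- sum(xc^2)
  ss_y <- sum(yc^2)
  if (ss_x == 0) abort("degenerate input: `x` has zero variance.")

  s <- crossprod(xc, yc) # p x m cross-product
  s0_norm <- sqrt(sum(s^2))
  if (s0_norm == 0) abort("degenerate input: `x` and `y` are uncorrelated constants.")

  r_mat <- matrix(0, p, n_factors) # weights
  t_mat <- matrix(0, n, n_factors) # x scores (orthonormal)
  p_mat <- matrix(0, p, n_factors) # x loadings
  q_mat <- matrix(0, m, n_factors) # y loadings
  v_mat <- matrix(0, p, n_factors) # orthonormal deflation basis

  achieved <- n_factors
  for (a in seq_len(n_factors)) {
    if (sqrt(sum(s^2)) <= 1e-12 * s0_norm) {
      warn(sprintf(
        "residual cross-product vanished after %d factor(s); requested %d.",
        a - 1L, n_factors
      ))
      achieved <- a - 1L
      break
    }
    r <- svd(s, nu = 1, nv = 0)$u[, 1]
    # fix the SVD sign ambiguity: largest-|entry| weight coefficient positive
    r <- r * sign(r[which.max(abs(r))])
    t_a <- xc %*% r
    t_a <- t_a - mean(t_a)
    normt <- sqrt(sum(t_a^2))
    if (normt <= 1e-12 * sqrt(ss_x)) {
      warn(sprintf(
        "x-score collapsed at factor %d; stopping with %d factor(s).",
        a, a - 1L
      ))
      achieved <- a - 1L
      break
    }
    t_a <- t_a / normt
    r <- r / normt
    p_a <- crossprod(xc, t_a)
    q_a <- crossprod(yc, t_a)
    v <- p_a
    if (a > 1) {
      basis <- v_mat[, seq_len(a - 1), drop = FALSE]
      v <- v - basis %*% crossprod(basis, v)
      v <- v - basis %*% crossprod(basis, v) # re-orthogonalize
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)

    r_mat[, a] <- r
    t_mat[, a] <- t_a
    p_mat[, a] <- p_a
    q_mat[, a] <- q_a
    v_mat[, a] <- v
  }
  if (achieved == 0) abort("no PLS factor could be extracted.")
  keep <- seq_len(achieved)
  r_mat <- r_mat[, keep, drop = FALSE]
  t_mat <- t_mat[, keep, drop = FALSE]
  p_mat <- p_mat[, keep, drop = FALSE]
  q_mat <- q_mat[, keep, drop = FALSE]

  b <- r_mat %*% t(q_mat)
  if (isTRUE(scale)) b <- b / x_scale

  # with orthonormal scores, each factor explains sum(p_a^2) of SS(Xc)
  x_var <- colSums(p_mat^2) / ss_x
  y_var <- if (ss_y > 0) colSums(q_mat^2) / ss_y else rep(NA_real_, achieved)

  comp_names <- colnames(y) %||% paste0("comp_", seq_len(m))
  wl_names <- colnames(x) %||% paste0("x", seq_len(p))
  dimnames(b) <- list(wl_names, comp_names)

  structure(
    list(
      x_mean = setNames(x_mean, wl_names),
      y_mean = setNames(y_mean, comp_names),
      x_scale = x_scale,
      scaled = isTRUE(scale),
      n_factors = achieved,
      n_samples = n,
      weights = r_mat,
      scores = t_mat,
      x_loadings = p_mat,
      y_loadings = q_mat,
      coefficients = b,
      x_variance_explained = x_var,
      y_variance_explained = y_var,
      components = comp_names,
      wavelengths = wavelengths
    ),
    class = "simpls"
  )
}

#' @export
print.simpls <- function(x, ...) {
  cat(sprintf(
    "<simpls> %d factor(s), %d predictors -> %d component(s), fit on %d samples\n",
    x$n_factors, nrow(x$coefficients), ncol(x$coefficients), x$n_samples
  ))
  cat(sprintf(
    " cumulative variance explained: X %.1f%%, Y %.1f%%\n",
    100 * sum(x$x_variance_explained), 100 * sum(x$y_variance_explained)
  ))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' Applies the calibrated regression-coefficient matrix:
#' \eqn{\hat y = \bar y + (x - \bar x) B}, a plain matrix multiplication.
#' Raw predictions can be negative; since concentrations are physically
#' nonnegative, a clamped variant (`max(0, raw)`) is always reported
#' alongside. Clamping is presentation-level only and is never fed back
#' into fitting.
#'
#' @param object A fitted [fit_simpls()] model.
#' @param newdata A numeric vector (one spectrum), a matrix of spectra in
#'   rows, or a wide spectra tibble (`wavelength_nm` plus sample columns,
#'   each column one spectrum).
#' @param ... Unused.
#'
#' @return A tibble with columns `sample`, `component`, `raw_ppm`,
#'   `clamped_ppm` (one row per sample x component).
#' @examples
#' sig <- cross_sections(default_voc_library(seed = 1))
#' singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
#' fit <- fit_simpls(build_reference_set(singles, noise_fraction = 0))
#' unknown <- pa_spectra(sig, c(`2-butanone` = 50, `1-propanol` = 50))
#' predict(fit, unknown)
#' @export
predict.simpls <- function(object, newdata, ...) {
  xm <- prediction_matrix(object, newdata)
  raw <- predict_raw(object, xm)
  tibble::tibble(
    sample = rep(rownames(raw), times = ncol(raw)),
    component = rep(colnames(raw), each = nrow(raw)),
    raw_ppm = as.vector(raw),
    clamped_ppm = pmax(as.vector(raw), 0)
  )
}

# Coerce predict() input to a samples-x-wavelengths matrix with row names.
prediction_matrix <- function(object, newdata) {
  p <- length(object$x_mean)
  if (is.data.frame(newdata) && "wavelength_nm" %in% names(newdata)) {
    parts <- split_spectra(newdata, arg = "newdata")
    xm <- t(parts$signals)
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    xm <- matrix(newdata, nrow = 1)
    rownames(xm) <- "sample_1"
  } else {
    xm <- as.matrix(newdata)
  }
  if (ncol(xm) != p) {
    abort(sprintf(
      "spectrum length %d does not match the model's %d wavelengths.",
      ncol(xm), p
    ))
  }
  if (is.null(rownames(xm))) rownames(xm) <- paste0("sample_", seq_len(nrow(xm)))
  xm
}

# Matrix-in, matrix-out prediction used internally (cross-validation etc.).
predict_raw <- function(object, xm) {
  raw <- sweep(xm, 2, object$x_mean) %*% object$coefficients
  raw <- sweep(raw, 2, object$y_mean, "+")
  colnames(raw) <- object$components
  raw
}

#' Per-factor and cumulative variance explained
#'
#' Fractions of the centered sum of squares of the predictors and responses
#' captured by each PLS factor, with their cumulative sums (nondecreasing
#' by construction).
#'
#' @param model A fitted [fit_simpls()] model.
#' @return A tibble with columns `factor`, `x_variance`, `y_variance`,
#'   `x_cumulative`, `y_cumulative`.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "simpls"))
  tibble::tibble(
    factor = seq_len(model$n_factors),
    x_variance = model$x_variance_explained,
    y_variance = model$y_variance_explained,
    x_cumulative = cumsum(model$x_variance_explained),
    y_cumulative = cumsum(model$y_variance_explained)
  )
}

#' @describeIn fit_simpls Tidy the regression-coefficient matrix into one
#'   row per wavelength and component (`term` carries the predictor name,
#'   `wavelength_nm` is filled when known).
#' @param x,... For `tidy.simpls`: the fitted model and unused arguments.
#' @export
tidy.simpls <- function(x, ...) {
  b <- x$coefficients
  out <- tibble::tibble(
    term = rep(rownames(b), times = ncol(b)),
    component = rep(colnames(b), each = nrow(b)),
    estimate = as.vector(b)
  )
  if (!is.null(x$wavelengths)) {
    out$wavelength_nm <- rep(x$wavelengths, times = ncol(b))
  }
  out
}

#' @describeIn fit_simpls One-row model summary: factor count, sample count,
#'   cumulative X- and Y-variance fractions.
#' @export
glance.simpls <- function(x, ...) {
  tibble::tibble(
    n_factors = x$n_factors,
    n_samples = x$n_samples,
    x_variance = sum(x$x_variance_explained),
    y_variance = sum(x$y_variance_explained)
  )
}
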