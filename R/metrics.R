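#' Residual summary statistics for concentration predictions
#'
#' The evaluation arithmetic used throughout the package. Residuals follow
#' the convention \eqn{\hat y - y} (predicted minus true), so a positive
#' bias means over-prediction. Multi-column inputs are pooled entrywise:
#' all components of all samples contribute to a single summary number.
#'
#' * `rmse()` — root mean square error, \eqn{\sqrt{\frac{1}{N}\sum (y_i -
#'   \hat y_i)^2}} over all N entries; the RMSEC when evaluated on the
#'   calibration set.
#' * `press()` — predicted residual error sum of squares,
#'   \eqn{\sum (y_i - \hat y_i)^2}; smaller is better. `press = N * rmse^2`
#'   exactly.
#' * `bias_and_std()` — mean residual, and sample standard deviation of the
#'   residuals (n - 1 denominator).
#'
#' @param y_true,y_hat Numeric vectors, matrices or data frames of matching
#'   shape, ppm.
#' @return `rmse()`: a single number, ppm. `press()`: a single number,
#'   ppm^2. `bias_and_std()`: a named numeric vector `c(bias =, std =)`,
#'   ppm.
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2)
#' press(c(0, 0), c(3, 4)) # 25
#' bias_and_std(c(0, 0), c(-1, 1)) # bias 0, std sqrt(2)
#' @export
rmse <- function(y_true, y_hat) {
  r <- pooled_residuals(y_true, y_hat)
  sqrt(mean(r^2))
}

#' @rdname rmse
#' @export
press <- function(y_true, y_hat) {
  r <- pooled_residuals(y_true, y_hat)
  sum(r^2)
}

#' @rdname rmse
#' @export
bias_and_std <- function(y_true, y_hat) {
  r <- pooled_residuals(y_true, y_hat)
  if (length(r) < 2) abort("need at least 2 residuals for a standard deviation.")
  c(bias = mean(r), std = sd(r))
}

pooled_residuals <- function(y_true, y_hat) {
  y_true <- as.matrix(y_true)
  y_hat <- as.matrix(y_hat)
  if (!all(dim(y_true) == dim(y_hat))) {
    abort("`y_true` and `y_hat` must have the same shape.")
  }
  if (length(y_true) == 0) abort("empty input.")
  as.vector(y_hat) - as.vector(y_true)
}

#' Clamp predicted concentrations at zero
#'
#' Concentrations are physically nonnegative, but an unconstrained linear
#' predictor can return negative values. Setting those to zero can only
#' move a prediction closer to (never farther from) a nonnegative truth, so
#' for nonnegative true concentrations clamping weakly reduces every
#' squared residual, hence PRESS and RMSE.
#'
#' @param y_hat Numeric vector, matrix or data frame of predictions, ppm.
#' @return The same object with every negative entry replaced by 0.
#' @export
clamp_nonnegative <- function(y_hat) {
  if (is.data.frame(y_hat)) {
    y_hat[] <- lapply(y_hat, function(col) pmax(col, 0))
    y_hat
  } else {
    pmax(y_hat, 0)
  }
}

#' One-row validation report
#'
#' Computes the full residual summary (n, bias, std, rmse, press) for the
#' raw predictions and, when `clamp = TRUE`, for the nonnegativity-clamped
#' predictions instead.
#'
#' @param y_true,y_hat Matching matrices/data frames/vectors, ppm.
#' @param clamp Report the clamped variant?
#' @return A one-row tibble: `variant`, `n`, `bias_ppm`, `std_ppm`,
#'   `rmse_ppm`, `press_ppm2`.
#' @seealso [validation_summary()] for both variants at once.
#' @export
validation_report <- function(y_true, y_hat, clamp = FALSE) {
  if (clamp) y_hat <- clamp_nonnegative(y_hat)
  bs <- bias_and_std(y_true, y_hat)
  tibble::tibble(
    variant = if (clamp) "clamped" else "raw",
    n = length(pooled_residuals(y_true, y_hat)),
    bias_ppm = bs[["bias"]],
    std_ppm = bs[["std"]],
    rmse_ppm = rmse(y_true, y_hat),
    press_ppm2 = press(y_true, y_hat)
  )
}

#' @rdname validation_report
#' @export
validation_summary <- function(y_true, y_hat) {
  dplyr::bind_rows(
    validation_report(y_true, y_hat, clamp = FALSE),
    validation_report(y_true, y_hat, clamp = TRUE)
  )
}
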