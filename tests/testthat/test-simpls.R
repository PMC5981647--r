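rand_problem <- function(n, p, m, seed) {
  set.seed(seed)
  list(x = matrix(rnorm(n * p), n, p), y = matrix(rnorm(n * m), n, m))
}

test_that("exact-interpolation limit: noiseless linear response is reproduced", {
  set.seed(1)
  x <- matrix(rnorm(30 * 5), 30, 5)
  b_true <- matrix(rnorm(5 * 2), 5, 2)
  y <- x %*% b_true
  fit <- fit_simpls(x, y, n_factors = 5)
  pred <- predict_mat(fit, x)
  expect_lt(max(abs(pred - y)) / max(abs(y)), 1e-8)
})

test_that("at full rank SIMPLS equals minimum-norm ordinary least squares", {
  for (seed in 1:20) {
    pr <- rand_problem(20, 5, 2, seed)
    fit <- fit_simpls(pr$x, pr$y, n_factors = 5)
    ols <- minnorm_ols_oracle(pr$x, pr$y)
    new <- matrix(rnorm(8 * 5), 8, 5)
    expect_lt(max(abs(predict_mat(fit, new) - ols(new))), 1e-6)
  }
})

test_that("univariate SIMPLS matches an independent NIPALS PLS1 at every factor count", {
  for (seed in 1:15) {
    pr <- rand_problem(12, 6, 1, seed)
    for (a in 1:4) {
      fit <- fit_simpls(pr$x, pr$y, n_factors = a)
      oracle <- nipals_pls1_oracle(pr$x, pr$y, a)
      new <- matrix(rnorm(5 * 6), 5, 6)
      expect_lt(max(abs(predict_mat(fit, new) - oracle(new))), 1e-8)
    }
  }
})

test_that("predictions match a literal transcription of the SIMPLS recursion", {
  for (seed in 1:15) {
    pr <- rand_problem(8, 5, 2, seed)
    for (a in 1:4) {
      fit <- fit_simpls(pr$x, pr$y, n_factors = a)
      oracle <- simpls_oracle(pr$x, pr$y, a)
      new <- matrix(rnorm(6 * 5), 6, 5)
      expect_lt(max(abs(predict_mat(fit, new) - oracle(new))), 1e-6)
    }
  }
})

test_that("fitting is deterministic with a fixed sign convention", {
  pr <- rand_problem(15, 8, 2, 3)
  f1 <- fit_simpls(pr$x, pr$y, n_factors = 4)
  f2 <- fit_simpls(pr$x, pr$y, n_factors = 4)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$weights, f2$weights)
  # sign convention: each weight vector's largest-|entry| is positive
  for (a in 1:4) {
    w <- f1$weights[, a]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("successive x-scores are orthonormal", {
  pr <- rand_problem(25, 10, 3, 7)
  fit <- fit_simpls(pr$x, pr$y, n_factors = 6)
  gram <- crossprod(fit$scores)
  expect_lt(max(abs(gram - diag(6))), 1e-8)
})

test_that("centering absorbs constant offsets in the predictors", {
  pr <- rand_problem(15, 6, 2, 11)
  fit0 <- fit_simpls(pr$x, pr$y, n_factors = 3)
  fit5 <- fit_simpls(pr$x + 5, pr$y, n_factors = 3)
  new <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(predict_mat(fit0, new), predict_mat(fit5, new + 5),
               tolerance = 1e-9)
})

test_that("predicting at the predictor mean returns the response mean", {
  pr <- rand_problem(15, 6, 2, 13)
  fit <- fit_simpls(pr$x, pr$y, n_factors = 3)
  pred <- predict(fit, colMeans(pr$x))
  expect_equal(pred$raw_ppm, unname(colMeans(pr$y)), tolerance = 1e-12)
})

test_that("prediction reports raw and clamped values in tidy form", {
  pr <- rand_problem(15, 6, 2, 17)
  fit <- fit_simpls(pr$x, pr$y, n_factors = 3)
  pred <- predict(fit, matrix(rnorm(3 * 6), 3, 6))
  expect_named(pred, c("sample", "component", "raw_ppm", "clamped_ppm"))
  expect_equal(nrow(pred), 6)
  expect_equal(pred$clamped_ppm, pmax(pred$raw_ppm, 0))
  expect_error(predict(fit, matrix(0, 2, 5)), "does not match")
})

test_that("degenerate inputs raise explicit errors; rank deficiency stops early", {
  expect_error(fit_simpls(matrix(1, 10, 4), matrix(rnorm(10), 10, 1), 2),
               "zero variance")
  pr <- rand_problem(10, 5, 1, 19)
  expect_error(fit_simpls(pr$x, pr$y, n_factors = 6), "at most")
  expect_error(fit_simpls(pr$x[1:3, ], pr$y[1:3, , drop = FALSE], 3), "exceed")

  # rank-2 predictors cannot support 4 factors: early stop with a warning
  set.seed(23)
  low <- matrix(rnorm(10 * 2), 10, 2) %*% matrix(rnorm(2 * 5), 2, 5)
  y <- matrix(rnorm(10), 10, 1)
  expect_warning(fit <- fit_simpls(low, y, n_factors = 4), "factor")
  expect_lte(fit$n_factors, 2)
})

test_that("variance explained is nondecreasing and reaches 1 in the noiseless limit", {
  set.seed(29)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- x %*% matrix(rnorm(6 * 2), 6, 2)
  fit <- fit_simpls(x, y, n_factors = 6)
  ve <- variance_explained(fit)
  expect_true(all(diff(ve$x_cumulative) >= -1e-12))
  expect_true(all(diff(ve$y_cumulative) >= -1e-12))
  expect_lte(max(ve$x_cumulative), 1 + 1e-10)
  expect_equal(ve$y_cumulative[6], 1, tolerance = 1e-10)
})

test_that("six factors explain most response variance on the noisy default library", {
  sig <- cross_sections(default_voc_library(seed = 1))
  singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
  for (seed in 1:5) {
    ref <- build_reference_set(singles, noise_fraction = 0.10,
                               noise_placement = "per_reference", seed = seed)
    fit <- fit_simpls(ref, n_factors = 6)
    expect_gt(sum(fit$y_variance_explained), 0.90)
  }
})

test_that("broom accessors expose coefficients and fit summary", {
  sig <- cross_sections(make_test_library(), make_test_grid())
  singles <- pa_spectra(sig, mixture_singles(names(sig)[-1], 100))
  ref <- build_reference_set(singles, noise_fraction = 0)
  fit <- fit_simpls(ref, n_factors = 3)

  td <- tidy(fit)
  expect_named(td, c("term", "component", "estimate", "wavelength_nm"))
  expect_equal(nrow(td), 41 * 3)

  gl <- glance(fit)
  expect_equal(gl$n_factors, 3)
  expect_equal(gl$y_variance, 1, tolerance = 1e-9)
})

test_that("JSON serialization round-trips a fitted model", {
  pr <- rand_problem(15, 6, 2, 31)
  fit <- fit_simpls(pr$x, pr$y, n_factors = 3)
  path <- tempfile(fileext = ".json")
  write_simpls(fit, path)
  back <- read_simpls(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$x_mean, fit$x_mean, tolerance = 1e-12)
  new <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(predict_mat(back, new), predict_mat(fit, new), tolerance = 1e-12)
  expect_error(read_simpls(tempfile()), "no such file")
})
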