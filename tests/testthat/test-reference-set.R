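test_that("concentration grid enumerates the balanced factorial design", {
  # one component: the four default levels in ppm
  g1 <- concentration_grid(c("a"))
  expect_equal(g1$a, c(0, 30, 70, 100))

  # two components, four factors: 16 unique rows
  g2 <- concentration_grid(c("a", "b"))
  expect_equal(nrow(g2), 16)
  expect_equal(nrow(dplyr::distinct(g2)), 16)

  # last component varies fastest
  expect_equal(g2$b[1:4], c(0, 30, 70, 100))
  expect_equal(g2$a[1:4], rep(0, 4))

  # balance: every component takes each level equally often
  counts <- apply(as.matrix(g2), 2, table)
  expect_true(all(counts == 4))
  g3 <- concentration_grid(3, scale_factors = c(0, 0.5, 1), base_concentration = 10)
  expect_true(all(apply(as.matrix(g3), 2, table) == 9))

  expect_error(concentration_grid("a", scale_factors = c(0, 1.5)), "\\[0, 1\\]")
  expect_error(concentration_grid("a", scale_factors = c(0.3, 0.3)), "distinct")
  expect_error(concentration_grid("a", base_concentration = 0), "positive")
})

test_that("reference set combines scaled singles in all factor combinations", {
  singles <- make_test_singles()

  # factors {0, 1}, one component: zero spectrum plus the original
  one <- build_reference_set(singles[c("wavelength_nm", "a")],
                             scale_factors = c(0, 1), noise_fraction = 0)
  expect_equal(nrow(one$x), 2)
  expect_equal(unname(one$x[1, ]), rep(0, 41))
  expect_equal(unname(one$x[2, ]), singles$a)
  expect_equal(one$y[, "a"], c(0, 100))

  # 3 components, 4 factors: 64 rows; all-ones row = sum of all singles
  ref <- build_reference_set(singles, noise_fraction = 0)
  expect_equal(nrow(ref$x), 4^3)
  all_on <- which(rowSums(ref$y) == 300)
  expect_equal(unname(ref$x[all_on, ]),
               singles$a + singles$b + singles$c)

  # exact reconstruction: X = F S with F the factor matrix
  f <- as.matrix(ref$y) / 100
  s <- t(as.matrix(singles[-1]))
  expect_equal(unname(ref$x), unname(f %*% s), tolerance = 1e-14)

  # Y is the factorial enumeration, all rows distinct
  expect_equal(nrow(unique(as.data.frame(ref$y))), 4^3)

  expect_error(build_reference_set(singles, scale_factors = c(0, 2)), "\\[0, 1\\]")
})

test_that("per-reference noise perturbs every row independently", {
  singles <- make_test_singles()
  ref <- build_reference_set(singles, noise_fraction = 0.1,
                             noise_placement = "per_reference", seed = 11)
  clean <- build_reference_set(singles, noise_fraction = 0)

  # rows are pairwise distinct (including the all-zero-concentration row,
  # whose noise scale is zero RMS -> stays zero, so exclude it)
  nz <- rowSums(clean$x^2) > 0
  x <- ref$x[nz, ]
  expect_equal(nrow(unique(as.data.frame(x))), sum(nz))

  # additivity of noiseless construction is broken by independent noise
  y <- ref$y
  r110 <- ref$x[y[, 1] == 100 & y[, 2] == 100 & y[, 3] == 0, ]
  r100 <- ref$x[y[, 1] == 100 & y[, 2] == 0 & y[, 3] == 0, ]
  r010 <- ref$x[y[, 1] == 0 & y[, 2] == 100 & y[, 3] == 0, ]
  expect_gt(max(abs(r110 - r100 - r010)), 1e-6)

  # determinism per seed
  again <- build_reference_set(singles, noise_fraction = 0.1,
                               noise_placement = "per_reference", seed = 11)
  expect_identical(ref$x, again$x)
})

test_that("originals-mode noise is exactly correlated across shared components", {
  singles <- make_test_singles()
  ref <- build_reference_set(singles, scale_factors = c(0, 1),
                             noise_fraction = 0.1,
                             noise_placement = "originals", seed = 5)
  y <- ref$y
  pick <- function(a, b, c) {
    ref$x[y[, "a"] == a & y[, "b"] == b & y[, "c"] == c, ]
  }
  # rows built from the same noisy originals add exactly: the (1,1,0) row
  # equals the (1,0,0) row plus the (0,1,0) row, noise included
  expect_equal(pick(100, 100, 0), pick(100, 0, 0) + pick(0, 100, 0),
               tolerance = 1e-14)
  expect_equal(pick(100, 100, 100),
               pick(100, 0, 0) + pick(0, 100, 0) + pick(0, 0, 100),
               tolerance = 1e-14)
})

test_that("zero noise fraction leaves the corpus unchanged in both modes", {
  singles <- make_test_singles()
  clean <- build_reference_set(singles, noise_fraction = 0)
  for (mode in c("per_reference", "originals")) {
    same <- build_reference_set(singles, noise_fraction = 0,
                                noise_placement = mode, seed = 99)
    expect_equal(same$x, clean$x)
  }
})
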