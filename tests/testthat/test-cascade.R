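test_that("uniform cascade (p = 0.5) is the uniform measure", {
  x <- binomial_cascade(10, 0.5)
  expect_length(x, 1024)
  expect_true(all(x == 2^-10))
})

test_that("three-level cascade equals brute-force multiplier enumeration", {
  p <- 0.3
  # every leaf mass is the product of its three branch weights
  paths <- expand.grid(l1 = c(p, 1 - p), l2 = c(p, 1 - p), l3 = c(p, 1 - p))
  # leaf order: level-1 choice varies slowest (left/right halves), level-3 fastest
  expected <- numeric(8)
  for (i in 0:7) {
    bits <- c(i %/% 4 %% 2, i %/% 2 %% 2, i %% 2)  # 0 = left at that level
    expected[i + 1] <- prod(ifelse(bits == 0, p, 1 - p))
  }
  expect_equal(binomial_cascade(3, p), expected)
})

test_that("cascade mass is conserved and non-negative at any depth", {
  for (prm in list(c(8, 0.25), c(12, 0.4), c(6, 0.49))) {
    x <- binomial_cascade(prm[1], prm[2])
    expect_length(x, 2^prm[1])
    expect_true(all(x >= 0))
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
})

test_that("random orientation is a seeded rearrangement of the same masses", {
  a <- binomial_cascade(8, 0.3, orientation = "random", seed = 7)
  b <- binomial_cascade(8, 0.3, orientation = "random", seed = 7)
  d <- binomial_cascade(8, 0.3)
  expect_identical(a, b)
  expect_equal(sort(a), sort(d))
})

test_that("cascade parameter validation rejects degenerate inputs", {
  expect_error(binomial_cascade(1, 0.3), "levels")
  expect_error(binomial_cascade(5, 0), "weight_p")
  expect_error(binomial_cascade(5, 1.2), "weight_p")
})

test_that("closed-form singularity strength matches its definition at q = +/-5", {
  p <- 0.25
  a_manual <- function(q)
    -(p^q * log(p) + (1 - p)^q * log(1 - p)) / ((p^q + (1 - p)^q) * log(2))
  expect_equal(cascade_alpha(-5, p), a_manual(-5))
  expect_equal(cascade_alpha(5, p), a_manual(5))
  # frozen oracle value used throughout the validation suite
  expect_equal(cascade_width_analytic(0.25, seq(-5, 5, 0.25)), 1.571971,
               tolerance = 1e-6)
})

test_that("AR(1) generator has the expected lag-1 autocorrelation", {
  w <- ar1_series(10000, 0, seed = 11)
  expect_lt(abs(stats::acf(w, plot = FALSE)$acf[2]), 0.03)
  x <- ar1_series(10000, 0.8, seed = 12)
  expect_lt(abs(stats::acf(x, plot = FALSE)$acf[2] - 0.8), 0.05)
})

test_that("AR(1) generator is deterministic under a fixed seed and validates phi", {
  expect_identical(ar1_series(64, 0.5, seed = 3), ar1_series(64, 0.5, seed = 3))
  expect_error(ar1_series(100, 1), "phi")
  expect_error(ar1_series(100, -1.2), "phi")
  expect_error(ar1_series(8, 0.5), "n")
})
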