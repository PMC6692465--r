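test_that("dyadic scale partition spans 4 .. n/4", {
  expect_identical(cj_scales(1024), as.integer(c(4, 8, 16, 32, 64, 128, 256)))
  expect_identical(cj_scales(16), 4L)
  expect_identical(cj_scales(1000), as.integer(c(4, 8, 16, 32, 64, 128)))
  expect_error(cj_scales(15), "n >= 16")
})

test_that("measure transformation normalizes and preserves profile shape", {
  expect_equal(cj_measure(rep(1, 8), "none"), rep(1 / 8, 8))
  m <- cj_measure(c(-1, 0, 1), "min-shift")
  expect_equal(m, c(0, 1 / 3, 2 / 3), tolerance = 1e-5)
  x <- ar1_series(500, 0.6, seed = 2)
  expect_equal(sum(cj_measure(x)), 1, tolerance = 1e-12)
  expect_equal(sum(cj_measure(x, "abs-increments")), 1, tolerance = 1e-12)
  expect_error(cj_measure(rep(3, 100), "min-shift"), "degenerate")
  expect_error(cj_measure(c(-1, 1, 2), "none"), "non-negative")
})

test_that("uniform measure gives alpha = f = 1 and zero width", {
  sp <- cj_spectrum(rep(2, 1024), shift_policy = "none")
  expect_true(all(sp$retained))
  expect_equal(sp$alpha, rep(1, length(sp$q)), tolerance = 1e-10)
  expect_equal(sp$f, rep(1, length(sp$q)), tolerance = 1e-10)
  expect_equal(sp$width, 0, tolerance = 1e-10)
})

test_that("spectrum slopes match an independent per-q regression", {
  # independent route: explicit bin sums, explicit mass weights, lm() fits
  x <- binomial_cascade(6, 0.3)          # n = 64 small instance
  n <- length(x)
  mu <- x / sum(x)
  qs <- c(-2, 0.5, 3)
  for (qv in qs) {
    ya <- yf <- lnL <- numeric(0)
    for (L in cj_scales(n)) {
      bins <- tapply(mu, rep(seq_len(n / L), each = L), sum)
      P <- bins / sum(bins)
      w <- P^qv / sum(P^qv)
      ya <- c(ya, sum(w * log(P)))
      yf <- c(yf, sum(w * log(w)))
      lnL <- c(lnL, log(L))
    }
    alpha_ref <- unname(coef(lm(ya ~ lnL))[2])
    f_ref <- unname(coef(lm(yf ~ lnL))[2])
    sp <- cj_spectrum(x, q = qs, shift_policy = "none")
    k <- match(qv, qs)
    expect_equal(sp$alpha[k], alpha_ref, tolerance = 1e-10)
    expect_equal(sp$f[k], f_ref, tolerance = 1e-10)
  }
})

test_that("cascade width grows with asymmetry and alpha decreases in q", {
  widths <- vapply(c(0.5, 0.4, 0.3, 0.25), function(p)
    cj_spectrum(binomial_cascade(12, p), shift_policy = "none")$width,
    numeric(1))
  expect_true(all(diff(widths) > 0))
  sp <- cj_spectrum(binomial_cascade(12, 0.3), shift_policy = "none")
  expect_true(all(diff(sp$alpha[sp$retained]) <= 1e-10))
})

test_that("width is invariant to positive rescaling of the measure", {
  x <- binomial_cascade(10, 0.35)
  w1 <- cj_spectrum(x, shift_policy = "none")$width
  w2 <- cj_spectrum(1000 * x, shift_policy = "none")$width
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("retained moment orders satisfy the fit-correlation threshold", {
  x <- ar1_series(1024, 0.9, seed = 8)
  sp <- cj_spectrum(x, r_min = 0.995)
  expect_true(all(abs(sp$r_alpha[sp$retained]) >= 0.995))
  expect_true(all(abs(sp$r_f[sp$retained]) >= 0.995))
  # tightening the threshold can only shrink the retained set
  sp2 <- cj_spectrum(x, r_min = 0.9999)
  expect_true(all(which(sp2$retained) %in% which(sp$retained)))
})
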