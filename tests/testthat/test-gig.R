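# GIG mixing distribution: omega, Bessel ratios, density, moments, sampler.

test_that("omega is sqrt(tau^2 + xi^2) - xi, stable near degeneracy", {
  expect_equal(gig_omega(0.5, 1), sqrt(1.25) - 1, tolerance = 1e-12)
  expect_equal(gig_omega(3, 4), 1, tolerance = 1e-12)
  # tiny tau must not underflow to exactly zero: Taylor limit tau^2 / (2 xi)
  w <- gig_omega(1e-8, 1)
  expect_gt(w, 0)
  expect_equal(w, 5e-17, tolerance = 1e-6)
  expect_error(gig_omega(-1, 1), "positive")
  expect_error(gig_omega(1, 0), "positive")
  expect_error(gig_params(0, 1), "tau")
})

test_that("Bessel ratio: order symmetry, half-integer closed forms, oracle", {
  xs <- c(1e-6, 1e-3, 0.1, 1, 10, 1e3, 1e4)
  # K_{1/2} = K_{-1/2} so the ratio at order -1/2 is exactly 1
  expect_equal(bessel_k_ratio(-1/2, xs), rep(1, length(xs)), tolerance = 1e-12)
  # K_{3/2}(x) = K_{1/2}(x) (1 + 1/x)
  expect_equal(bessel_k_ratio(1/2, xs), 1 + 1 / xs, tolerance = 1e-10)
  # negative half-integer closed forms from K_{n+1/2}(x) = K_{1/2}(x) *
  # sum_k (n+k)! / (k! (n-k)!) (2x)^{-k}: R_{-3/2} = K_{1/2}/K_{3/2},
  # R_{-5/2} = K_{3/2}/K_{5/2}
  for (x in c(1e-4, 0.05, 1, 50)) {
    k32 <- 1 + 1 / x
    k52 <- 1 + 3 / x + 3 / x^2
    expect_equal(bessel_k_ratio(-1/2, x), 1, tolerance = 1e-10)
    expect_equal(bessel_k_ratio(-3/2, x), 1 / k32, tolerance = 1e-10)
    expect_equal(bessel_k_ratio(-5/2, x), k32 / k52, tolerance = 1e-10)
  }
  # independent integral-representation oracle
  expect_equal(bessel_k_ratio(0, 1),
               bessel_k_integral(1, 1) / bessel_k_integral(0, 1),
               tolerance = 1e-10)
  expect_equal(bessel_k_ratio(0, 1), 1.42962, tolerance = 1e-5)
  expect_equal(exp(log_bessel_k(7/2, 0.3)),
               bessel_k_integral(7/2, 0.3), tolerance = 1e-9)
  expect_error(bessel_k_ratio(1, -2), "positive")
})

test_that("log-scale Bessel evaluation survives large orders", {
  # naive besselK overflows here; the recurrence must not
  lk <- log_bessel_k(500.5, 3)
  expect_true(is.finite(lk))
  expect_true(is.infinite(besselK(3, 500.5)))
  # spot-check against the symmetry + small-order base
  expect_equal(log_bessel_k(-10.5, 2), log_bessel_k(10.5, 2))
  expect_equal(exp(log_bessel_k(10.5, 2)), besselK(2, 10.5), tolerance = 1e-12)
})

test_that("GIG density normalizes, matches the classical parametrization and mode", {
  for (g in c(-1/2, -3/2, -5/2, 0.7)) {
    for (tx in list(c(0.5, 1), c(2, 0.5), c(0.1, 3))) {
      p <- gig_params(tx[1], tx[2], g)
      z <- stats::integrate(function(v) dgig(v, p), 0, Inf, rel.tol = 1e-10)
      expect_equal(z$value, 1, tolerance = 1e-8)
    }
  }
  # classical GIG(a, b, p) density with a = omega/xi, b = omega*xi
  p <- gig_params(0.5, 1, -1/2)
  a <- p$omega / p$xi
  b <- p$omega * p$xi
  classical <- function(v) {
    (a / b)^(p$gamma / 2) / (2 * besselK(sqrt(a * b), p$gamma)) *
      v^(p$gamma - 1) * exp(-(a * v + b / v) / 2)
  }
  for (v in c(0.5, 1, 2)) {
    expect_equal(dgig(v, p), classical(v), tolerance = 1e-12)
  }
  # mode formula for gamma < 1 vs grid search
  p2 <- gig_params(1.3, 0.8, -3/2)
  mode_formula <- p2$xi * ((p2$gamma - 1) +
                             sqrt((p2$gamma - 1)^2 + p2$omega^2)) / p2$omega
  grid <- seq(1e-4, 5, by = 1e-4)
  expect_equal(grid[which.max(dgig(grid, p2))], mode_formula, tolerance = 1e-3)
  expect_error(dgig(-1, p2), "positive")
})

test_that("GIG moments match quadrature and have the Bessel-ratio form", {
  p <- gig_params(0.5, 1, -1/2)
  expect_equal(gig_moment(p, 0), 1)
  expect_equal(gig_moment(p, 1), 1, tolerance = 1e-12) # xi * R_{-1/2} = xi
  expect_equal(gig_moment(p, 1), gig_moment_quad(p, 1), tolerance = 1e-8)
  p2 <- gig_params(0.5, 1, -3/2)
  expect_equal(gig_moment(p2, 2), gig_moment_quad(p2, 2), tolerance = 1e-6)
  expect_gt(gig_variance(p2), 0)
  # large tau: variance shrinks towards the degenerate-mixing limit
  expect_lt(gig_variance(gig_params(50, 1, -1/2)),
            gig_variance(gig_params(0.5, 1, -1/2)))
  expect_error(gig_moment(p, -1), "non-negative")
})

test_that("GIG sampler is reproducible and Monte-Carlo consistent", {
  p <- gig_params(0.5, 1, -1/2)
  x <- rgig(1e5, p, seed = 42)
  expect_identical(x, rgig(1e5, p, seed = 42))
  se1 <- sqrt(gig_variance(p) / 1e5)
  expect_lt(abs(mean(x) - gig_moment(p, 1)), 3 * se1)
  m2 <- gig_moment(p, 2)
  se2 <- sqrt((gig_moment(p, 4) - m2^2) / 1e5)
  expect_lt(abs(mean(x^2) - m2), 3 * se2)
  # general (Devroye) path for gamma = -3/2, checked against moments
  p2 <- gig_params(0.8, 1.5, -3/2)
  x2 <- rgig(2e4, p2, seed = 7)
  expect_lt(abs(mean(x2) - gig_moment(p2, 1)),
            3 * sqrt(gig_variance(p2) / 2e4))
  m2b <- gig_moment(p2, 2)
  expect_lt(abs(mean(x2^2) - m2b),
            3 * sqrt((gig_moment(p2, 4) - m2b^2) / 2e4))
  # sampling variance tracks the formula at large tau too
  p3 <- gig_params(20, 1, -1/2)
  x3 <- rgig(1e5, p3, seed = 9)
  expect_equal(stats::var(x3), gig_variance(p3), tolerance = 0.05)
})
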