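# Common-shock multivariate Poisson and its GIG mixture.

test_that("multivariate Poisson pmf: cells, support law, normalization", {
  expect_equal(dmvpois(c(0, 0), c(1, 1)), exp(-2), tolerance = 1e-12)
  expect_equal(dmvpois(c(1, 0), c(1, 1)), 0) # y2 < y1 off support
  g <- grid_counts(30)
  expect_equal(sum(dmvpois(g, c(1, 1))), 1, tolerance = 1e-10)
  # trivariate cell by hand: y = (1, 2, 1), lambda = (0.5, 1, 0.3)
  expect_equal(dmvpois(c(1, 2, 1), c(0.5, 1, 0.3)),
               exp(-1.8) * 0.5 * 1 * 0.3^0, tolerance = 1e-12)
  expect_error(dmvpois(c(-1, 0), c(1, 1)), "non-negative")
  expect_error(dmvpois(c(0, 0), c(0, 1)), "shock")
})

test_that("multivariate Poisson sampler has shock moments and support", {
  lam <- c(0.7, 1.4, 2.1)
  y <- rmvpois(1e5, lam, seed = 11)
  expect_identical(y, rmvpois(1e5, lam, seed = 11))
  expect_true(all(y[, 2] >= y[, 1]), TRUE)
  for (j in 2:3) {
    mu <- lam[j] + lam[1]
    expect_lt(abs(mean(y[, j]) - mu), 3 * sqrt(mu / 1e5))
  }
  # shared-shock covariance Cov(Y2, Y3) = lambda_1
  cv <- stats::cov(y[, 2], y[, 3])
  expect_lt(abs(cv - lam[1]), 4 * sqrt(2) * lam[1] / sqrt(1e5) + 0.02)
  # near-zero shock rate: component 1 almost surely zero
  y0 <- rmvpois(1e4, c(1e-8, 1), seed = 2)
  expect_lt(mean(y0[, 1]), 1e-3)
})

test_that("closed-form mixed pmf equals the quadrature mixture on the grid", {
  lam <- c(0.5, 1.5)
  ys <- rbind(c(0, 0), c(1, 1), c(1, 2), c(2, 3))
  for (g in c(-1/2, -3/2, -5/2)) {
    p <- gig_params(0.5, 1, g)
    for (i in seq_len(nrow(ys))) {
      closed <- dmcpgig(ys[i, ], lam, p)
      oracle <- dmcpgig_quad(ys[i, ], lam, p)
      expect_lt(abs(closed / oracle - 1), 1e-8)
    }
  }
  # support violation and zero-rate edge cases
  p <- gig_params(0.5, 1, -1/2)
  expect_equal(dmcpgig(c(2, 1), lam, p), 0)
  expect_equal(dmcpgig_quad(c(2, 1), lam, p), 0)
  expect_gt(dmcpgig(c(1, 1), c(0.5, 0), p), 0) # zero non-shock rate allowed
  expect_equal(dmcpgig(c(1, 2), c(0.5, 0), p), 0)
})

test_that("all-zero cell equals the GIG Laplace transform at the total rate", {
  lam <- c(1, 1)
  for (g in c(-1/2, -5/2)) {
    p <- gig_params(0.5, 1, g)
    expect_equal(dmcpgig(c(0, 0), lam, p), gig_laplace(sum(lam), p),
                 tolerance = 1e-10)
    expect_equal(dmcpgig_quad(c(0, 0), lam, p), gig_laplace(sum(lam), p),
                 tolerance = 1e-8)
  }
})

test_that("mixed pmf normalizes within the tail-bound truncation", {
  lam <- c(0.5, 1.5)
  p <- gig_params(0.5, 1, -1/2)
  r <- mcpgig_trunc_radius(lam, p, defect = 1e-7)
  g <- grid_counts(r)
  expect_equal(sum(dmcpgig(g, lam, p)), 1, tolerance = 1e-6)
  # a faster-mixing setting certifies with a small radius
  p2 <- gig_params(3, 1, -3/2)
  r2 <- mcpgig_trunc_radius(lam, p2, defect = 1e-7)
  expect_lt(r2, 150)
  expect_equal(sum(dmcpgig(grid_counts(r2), lam, p2)), 1, tolerance = 1e-6)
})

test_that("degenerate mixing limit recovers the multivariate Poisson", {
  lam <- c(0.5, 1.5)
  ys <- grid_counts(15)
  dev <- sapply(c(10, 50, 200), function(tau) {
    p <- gig_params(tau, 1, -1/2)
    scale <- gig_moment(p, 1) # rates scaled by the degenerate mixing mean
    max(abs(dmcpgig(ys, lam, p) - dmvpois(ys, lam * scale)))
  })
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 2e-3)
})

test_that("mixed moments: formulas, overdispersion, Monte-Carlo agreement", {
  lam <- c(0.5, 1.5)
  p <- gig_params(0.5, 1, -1/2)
  mo <- mcpgig_moments(lam, p)
  expect_equal(mo$mean[2], 2, tolerance = 1e-12) # xi (lam2 + lam1) R = 2
  expect_true(all(mo$variance >= mo$mean))
  y <- rmcpgig(1e5, lam, p, seed = 5)
  expect_identical(y, rmcpgig(1e5, lam, p, seed = 5))
  for (j in 1:2) {
    expect_lt(abs(mean(y[, j]) - mo$mean[j]),
              3 * sqrt(mo$variance[j] / 1e5))
  }
  # sample variance within a loose Monte-Carlo band (4th-moment heavy tails)
  expect_equal(stats::var(y[, 2]), mo$variance[2], tolerance = 0.1)
})

test_that("shared frailty adds correlation beyond the pure common shock", {
  lam <- c(0.5, 1.5, 1.0)
  p <- gig_params(0.5, 1, -1/2)
  ymix <- rmcpgig(5e4, lam, p, seed = 21)
  ymp <- rmvpois(5e4, lam, seed = 22)
  cor_mix <- stats::cor(ymix[, 2], ymix[, 3])
  cor_mp <- stats::cor(ymp[, 2], ymp[, 3])
  expect_gt(cor_mix, 0)
  expect_gt(cor_mix, cor_mp)
})
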