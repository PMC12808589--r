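# Mean structure, rate map, likelihood, score, BHHH fitting.

test_that("mean structure: offsets, exposure linearity, arithmetic", {
  d <- tibble::tibble(y1 = c(0L, 0L), y2 = c(0L, 1L),
                      q1 = c(2, 3), q2 = c(2, 3),
                      x1 = c(0, 10), x2 = c(0, 10))
  pan <- count_panel(d, responses = c("y1", "y2"),
                     predictors = c("x1", "x2"), exposures = c("q1", "q2"))
  beta <- cbind(c(-5, -0.05, 0.4), c(1, 0.07, 0.05))
  mu <- mean_structure(pan, beta)
  # zero predictors: mu = q e^{intercept}
  expect_equal(mu$y1[1], 2 * exp(-5), tolerance = 1e-12)
  # x = (10, 10), q = 1 scaled by 3: exp(-5 - 0.5 + 4) = exp(-1.5)
  expect_equal(mu$y1[2] / 3, exp(-1.5), tolerance = 1e-12)
  # doubling exposure doubles the mean
  d2 <- d; d2$q1 <- d$q1 * 2; d2$q2 <- d$q2 * 2
  pan2 <- count_panel(d2, responses = c("y1", "y2"),
                      predictors = c("x1", "x2"), exposures = c("q1", "q2"))
  expect_equal(as.matrix(mean_structure(pan2, beta)), 2 * as.matrix(mu),
               tolerance = 1e-12)
})

test_that("rate map round-trips the means and flags infeasibility", {
  fx <- tiny_panel(seed = 5)
  for (g in c(-1/2, -3/2)) {
    p <- gig_params(0.7, 1.3, g)
    lam <- rates_from_coefficients(fx$panel, fx$truth$beta, p)
    expect_true(all(lam$.feasible))
    # xi R (lam_j + lam_1) recovers mu exactly
    r <- bessel_k_ratio(g, p$omega)
    mu <- as.matrix(mean_structure(fx$panel, fx$truth$beta))
    back <- cbind(lam$y1, lam$y2 + lam$y1) * p$xi * r
    expect_equal(back, unname(mu), tolerance = 1e-10)
  }
  # gamma = -1/2, xi = 1: divisor is exactly 1
  p1 <- gig_params(0.5, 1, -1/2)
  mu <- as.matrix(mean_structure(fx$panel, fx$truth$beta))
  lam <- rates_from_coefficients(fx$panel, fx$truth$beta, p1)
  expect_equal(lam$y1, unname(mu[, 1]), tolerance = 1e-12)
  expect_equal(lam$y2, unname(mu[, 2] - mu[, 1]), tolerance = 1e-12)
  # swapped intercepts make the non-shock mean fall below the shock mean
  beta_bad <- fx$truth$beta[, 2:1]
  lam_bad <- rates_from_coefficients(fx$panel, beta_bad, p1)
  expect_false(any(lam_bad$.feasible))
})

test_that("log-likelihood agrees with the quadrature oracle and is exchangeable", {
  fx <- tiny_panel(n = 5, seed = 8)
  p <- gig_params(0.5, 1, -1/2)
  ll <- mcpgigr_loglik(fx$panel, fx$truth$beta, p)
  lam <- rates_from_coefficients(fx$panel, fx$truth$beta, p)
  y <- as.matrix(fx$panel$data[fx$panel$responses])
  ll_oracle <- sum(sapply(seq_len(5), function(i) {
    log(dmcpgig_quad(y[i, ], c(lam$y1[i], lam$y2[i]), p))
  }))
  expect_equal(ll, ll_oracle, tolerance = 1e-6)
  # permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  pp <- fx$panel
  pp$data <- pp$data[perm, ]
  expect_equal(mcpgigr_loglik(pp, fx$truth$beta, p), ll, tolerance = 1e-10)
})

test_that("likelihood is invariant to relabeling non-shock components", {
  tr <- truth_m3()
  design <- sim_design(40, seed = 31)
  panel <- simulate_panel(design, tr, seed = 32)
  p <- gig_params(tr$tau, tr$xi, tr$gamma)
  ll <- mcpgigr_loglik(panel, tr$beta, p)
  swapped <- panel
  swapped$data <- dplyr::rename(panel$data, y2 = "y3", y3 = "y2")
  expect_equal(mcpgigr_loglik(swapped, tr$beta[, c(1, 3, 2)], p), ll,
               tolerance = 1e-10)
})

test_that("analytic scores match central finite differences", {
  withr::local_seed(99)
  fx <- tiny_panel(seed = 12)
  for (g in c(-1/2, -3/2)) {
    for (rep in 1:3) {
      beta <- fx$truth$beta + matrix(stats::rnorm(6, 0, 0.05), 3, 2)
      p <- gig_params(exp(log(0.5) + stats::rnorm(1, 0, 0.2)),
                      exp(stats::rnorm(1, 0, 0.2)), g)
      Ga <- mcpgigr_score(fx$panel, beta, p)
      Gf <- mcpgigr_score(fx$panel, beta, p, method = "fd", h = 1e-5)
      expect_lt(max_rel_err(Ga, Gf), 1e-5)
    }
  }
  # trivariate panel exercises the shared-shock cross terms
  tr <- truth_m3()
  pan3 <- simulate_panel(sim_design(15, seed = 44), tr, seed = 45)
  p3 <- gig_params(0.6, 0.9, -3/2)
  Ga <- mcpgigr_score(pan3, tr$beta, p3)
  Gf <- mcpgigr_score(pan3, tr$beta, p3, method = "fd", h = 1e-5)
  expect_lt(max_rel_err(Ga, Gf), 1e-5)
  # column sums equal the finite-difference gradient of the whole likelihood
  g_total <- colSums(Ga)
  theta <- c(tr$beta, log(0.6), log(0.9))
  num <- sapply(seq_along(theta), function(j) {
    h <- 1e-6 * max(1, abs(theta[j]))
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    pu <- gig_params(exp(up[10]), exp(up[11]), -3/2)
    pd <- gig_params(exp(dn[10]), exp(dn[11]), -3/2)
    (mcpgigr_loglik(pan3, matrix(up[1:9], 3, 3), pu) -
        mcpgigr_loglik(pan3, matrix(dn[1:9], 3, 3), pd)) / (2 * h)
  })
  expect_equal(g_total, num, tolerance = 1e-4)
  # infeasible evaluation errors
  expect_error(mcpgigr_score(fx$panel, fx$truth$beta[, 2:1],
                             gig_params(0.5, 1, -1/2)),
               "infeasible")
})

test_that("initialization lands near the truth and handles degenerate panels", {
  design <- sim_design(300, seed = 61)
  panel <- simulate_panel(design, sim_truth(), seed = 62)
  init <- initialize_coefficients(panel)
  expect_true(all(abs(init$beta - sim_truth()$beta) < 1))
  expect_equal(init$xi, 1)
  expect_lt(abs(init$tau - 0.5), 0.4)
  # (at-most-)equidispersed data start at the upper clamp, the Poisson limit
  d_const <- tibble::tibble(y1 = rep(1L, 30), y2 = rep(3L, 30),
                            x1 = seq(0, 1, length.out = 30))
  pan_const <- count_panel(d_const, responses = c("y1", "y2"),
                           predictors = "x1")
  expect_equal(initialize_coefficients(pan_const)$tau, 50)
  # an all-zero response column takes the fallback intercept path
  d <- tibble::tibble(y1 = rep(0L, 20), y2 = rpois(20, 2), x1 = runif(20))
  d$y2 <- pmax(d$y2, d$y1)
  pan0 <- count_panel(d, responses = c("y1", "y2"), predictors = "x1")
  init0 <- initialize_coefficients(pan0)
  expect_true(all(is.finite(init0$beta)))
  expect_equal(init0$beta["x1", "y1"], 0)
})

test_that("BHHH fit recovers the truth with a monotone trace in few iterations", {
  design <- sim_design(300, seed = 71)
  panel <- simulate_panel(design, sim_truth(), seed = 72)
  fit <- fit_mcpgigr(panel)
  expect_true(fit$converged)
  expect_lt(fit$iterations, 30)
  expect_false(is.unsorted(fit$trace$loglik))
  # slope estimates within ~3 reported SEs of the generating truth
  truth <- sim_truth()$beta
  z <- (fit$beta - truth) / fit$se_beta
  expect_true(all(abs(z[-1, ]) < 3.5))
  # first-order condition at the optimum
  expect_lt(max(abs(fit$gradient)), 1e-3)
  # covariance symmetric with non-negative diagonal
  expect_equal(fit$covariance, t(fit$covariance), tolerance = 1e-12)
  expect_true(all(diag(fit$covariance) >= 0))
})

test_that("scaling all exposures shifts intercepts by -log(c) at the optimum", {
  withr::local_seed(81)
  design <- sim_design(150, seed = 81)
  design$q1 <- stats::runif(150, 0.5, 2)
  design$q2 <- stats::runif(150, 0.5, 2)
  panel <- simulate_panel(design, sim_truth(), seed = 82)
  fit1 <- fit_mcpgigr(panel)
  d2 <- panel$data
  d2$q1 <- d2$q1 * 5
  d2$q2 <- d2$q2 * 5
  panel2 <- count_panel(d2, responses = panel$responses,
                        predictors = panel$predictors,
                        exposures = panel$exposures)
  fit2 <- fit_mcpgigr(panel2)
  expect_equal(fit2$beta[1, ], fit1$beta[1, ] - log(5), tolerance = 1e-4)
  expect_equal(fit2$beta[-1, ], fit1$beta[-1, ], tolerance = 1e-4)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  fits <- lapply(c(150, 600), function(n) {
    design <- sim_design(n, seed = 91 + n)
    fit_mcpgigr(simulate_panel(design, sim_truth(), seed = 92 + n))
  })
  ratio <- fits[[1]]$se_beta["x1", "y2"] / fits[[2]]$se_beta["x1", "y2"]
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
  expect_true(all(is.finite(standard_errors(fits[[2]]))))
})

test_that("Poisson baseline: recovery on equidispersed data, nesting on mixed data", {
  design <- sim_design(300, seed = 101)
  mp_panel <- simulate_panel(design, sim_truth(), family = "mp", seed = 102)
  fit <- fit_mpr(mp_panel)
  expect_true(fit$converged)
  expect_false(is.unsorted(fit$trace$loglik))
  z <- (fit$beta - sim_truth()$beta) / fit$se_beta
  expect_true(all(abs(z[-1, ]) < 3.5))
  # on overdispersed data the mixed model dominates in likelihood
  mix_panel <- simulate_panel(design, sim_truth(), seed = 103)
  expect_lt(fit_mpr(mix_panel)$loglik, fit_mcpgigr(mix_panel)$loglik)
  # intercept-only baseline reproduces component means exactly
  null <- fit_mpr(mix_panel, intercept_only = TRUE)
  y <- as.matrix(mix_panel$data[mix_panel$responses])
  expect_equal(unname(exp(null$beta[1, ])), unname(colMeans(y)),
               tolerance = 1e-6)
})

test_that("single-coefficient Wald and likelihood-ratio statistics agree to first order", {
  design <- sim_design(600, seed = 111)
  panel <- simulate_panel(design, sim_truth(), seed = 112)
  full <- fit_mcpgigr(panel)
  restricted <- fit_mcpgigr(panel, constrain_zero = "y2:x1")
  expect_equal(unname(restricted$beta["x1", "y2"]), 0)
  g2 <- 2 * (full$loglik - restricted$loglik)
  z2 <- (full$beta["x1", "y2"] / full$se_beta["x1", "y2"])^2
  expect_gt(g2, 0)
  expect_lt(abs(g2 - z2) / z2, 0.3)
})
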