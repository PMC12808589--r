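# Shared helpers: independent oracles and tiny panel builders.

# Modified Bessel K via its integral representation; independent of besselK().
bessel_k_integral <- function(nu, x) {
  stats::integrate(function(t) exp(-x * cosh(t)) * cosh(nu * t),
                   0, 50, rel.tol = 1e-12)$value
}

# GIG Laplace transform E[exp(-s nu)] in closed form.
gig_laplace <- function(s, params) {
  a <- params$omega / params$xi
  b <- params$omega * params$xi
  exp((params$gamma / 2) * (log(a) - log(a + 2 * s)) +
        log_bessel_k(params$gamma, sqrt(b * (a + 2 * s))) -
        log_bessel_k(params$gamma, sqrt(b * a)))
}

# Raw GIG moment by adaptive quadrature of the density.
gig_moment_quad <- function(params, k) {
  stats::integrate(function(v) v^k * dgig(v, params), 0, Inf,
                   rel.tol = 1e-10)$value
}

# Full truncated support grid for a bivariate count model.
grid_counts <- function(upper) {
  as.matrix(expand.grid(y1 = 0:upper, y2 = 0:upper))
}

# A small deterministic panel with its generating truth.
tiny_panel <- function(n = 10, seed = 1) {
  fx <- make_fixture("small-panel", seed = seed)
  fx$panel <- local({
    p <- fx$panel
    p$data <- utils::head(p$data, n)
    p$n <- nrow(p$data)
    p
  })
  fx
}

# Trivariate truth whose means keep the shock component dominated everywhere
# on the (0,10)^2 predictor square.
truth_m3 <- function() {
  sim_truth(beta = cbind(c(-2, 0.01, 0.02), c(0.5, 0.05, 0.03),
                         c(1, 0.02, 0.04)),
            tau = 0.5, xi = 1)
}

max_rel_err <- function(a, b, floor = 1e-3) {
  max(abs(a - b) / pmax(abs(b), floor))
}
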