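#' Generalized inverse Gaussian parameter set
#'
#' Bundles the three parameters of the GIG mixing distribution used throughout
#' the package together with the derived Bessel argument
#' \eqn{\varpi = \sqrt{\tau^2 + \xi^2} - \xi}. The density is
#' \deqn{g(\nu) = \frac{\xi^{-\gamma}}{2 K_\gamma(\varpi)} \nu^{\gamma - 1}
#'   \exp\left(-\frac{\varpi}{2}\left(\frac{\nu}{\xi} +
#'   \frac{\xi}{\nu}\right)\right), \quad \nu > 0,}
#' i.e. a GIG law with classical parameters \eqn{a = \varpi/\xi},
#' \eqn{b = \varpi\xi} and order \eqn{\gamma}. \eqn{\tau} controls the
#' dispersion of the frailty, \eqn{\xi} its scale, and \eqn{\gamma} the tail
#' behaviour (half-integers such as \eqn{-1/2} give tractable Bessel forms).
#'
#' @param tau Positive dispersion parameter of the GIG random effect.
#' @param xi Positive scale parameter.
#' @param gamma Real shape (order) parameter; typically a negative
#'   half-integer.
#'
#' @return An object of class `gig_params`: a list with elements `tau`, `xi`,
#'   `gamma` and the derived `omega`.
#' @examples
#' p <- gig_params(tau = 0.5, xi = 1, gamma = -1/2)
#' p$omega # sqrt(1.25) - 1
#' @export
gig_params <- function(tau, xi, gamma = -1/2) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(xi), length(xi) == 1L, is.finite(xi),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (tau <= 0) stop("`tau` must be strictly positive (degenerate mixing is not a GIG).")
  if (xi <= 0) stop("`xi` must be strictly positive.")
  structure(
    list(tau = tau, xi = xi, gamma = gamma, omega = gig_omega(tau, xi)),
    class = "gig_params"
  )
}

#' @export
print.gig_params <- function(x, ...) {
  cat(sprintf("GIG mixing parameters: tau = %g, xi = %g, gamma = %g (omega = %g)\n",
              x$tau, x$xi, x$gamma, x$omega))
  invisible(x)
}

#' Derived GIG Bessel argument
#'
#' Computes \eqn{\varpi = \sqrt{\tau^2 + \xi^2} - \xi}, the argument of every
#' modified Bessel factor in the mixed count distribution. Evaluated as
#' `tau^2 / (sqrt(tau^2 + xi^2) + xi)` so the result does not lose precision
#' (or silently underflow to zero) when `tau` is tiny relative to `xi`.
#'
#' @param tau,xi Positive reals.
#' @return A strictly positive scalar.
#' @examples
#' gig_omega(3, 4) # 1
#' @export
gig_omega <- function(tau, xi) {
  if (!is.numeric(tau) || !is.numeric(xi) || any(tau <= 0) || any(xi <= 0)) {
    stop("`tau` and `xi` must be strictly positive.")
  }
  tau^2 / (sqrt(tau^2 + xi^2) + xi)
}

#' Log of the modified Bessel function of the second kind
#'
#' Evaluates \eqn{\log K_\nu(x)} stably for arbitrary real order, including
#' the large orders (of size `max(counts) + gamma`) that arise in the mixed
#' pmf, where a naive `besselK()` call overflows. Uses the symmetry
#' \eqn{K_{-\nu} = K_\nu}, exponentially scaled base evaluations at orders in
#' \eqn{[0, 2)}, and the (upward-stable) recurrence
#' \eqn{K_{\nu+1}(x) = K_{\nu-1}(x) + (2\nu/x) K_\nu(x)} carried in the log
#' domain.
#'
#' @param nu Real order(s).
#' @param x Positive argument(s); recycled against `nu`.
#' @return `log(K_nu(x))`, same length as the recycled inputs.
#' @examples
#' log_bessel_k(0.5, 2) # log(sqrt(pi/4) * exp(-2))
#' @export
log_bessel_k <- function(nu, x) {
  if (!is.numeric(nu) || !is.numeric(x)) stop("`nu` and `x` must be numeric.")
  if (any(!is.finite(x)) || any(x <= 0)) stop("Bessel argument `x` must be positive and finite.")
  n_out <- max(length(nu), length(x))
  nu <- abs(rep_len(as.numeric(nu), n_out))
  x <- rep_len(as.numeric(x), n_out)

  steps <- floor(nu)
  f <- nu - steps
  l0 <- log(besselK(x, f, expon.scaled = TRUE)) - x
  l1 <- log(besselK(x, f + 1, expon.scaled = TRUE)) - x
  out <- ifelse(steps == 0, l0, l1)
  kmax <- max(steps)
  if (kmax >= 2) {
    a <- l0
    b <- l1
    for (k in 2:kmax) {
      idx <- which(steps >= k)
      if (!length(idx)) break
      ord <- f[idx] + k - 1
      # K_{ord+1} = K_{ord-1} + (2 ord / x) K_ord, in logs; a <= b always
      # since K is increasing in non-negative order.
      new <- b[idx] + log(2 * ord / x[idx] + exp(a[idx] - b[idx]))
      a[idx] <- b[idx]
      b[idx] <- new
      out[idx] <- new
    }
  }
  out
}

#' Bessel ratio R_nu(x) = K_{nu+1}(x) / K_nu(x)
#'
#' The workhorse ratio appearing in GIG moments and in the score of the mixed
#' regression model. Computed through [log_bessel_k()] so it stays finite and
#' accurate for arguments from about 1e-6 up to 1e4 and for large orders.
#' By the order symmetry of K, `bessel_k_ratio(-1/2, x)` is exactly 1.
#'
#' @param order Real order(s) \eqn{\nu}.
#' @param x Positive argument(s).
#' @return The positive ratio, recycled to the common length.
#' @examples
#' bessel_k_ratio(-1/2, 3) # 1
#' bessel_k_ratio(1/2, 1) # 2: K_{3/2}(x) = K_{1/2}(x) (1 + 1/x)
#' @export
bessel_k_ratio <- function(order, x) {
  exp(log_bessel_k(order + 1, x) - log_bessel_k(order, x))
}

#' GIG density
#'
#' Density of the mixing distribution (see [gig_params()] for the
#' parametrization). Vectorized in `x`.
#'
#' @param x Positive evaluation points.
#' @param params A [gig_params()] object.
#' @param log Return the log density?
#' @return Density values (or their logs).
#' @examples
#' dgig(1, gig_params(0.5, 1, -1/2))
#' @export
dgig <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "gig_params"))
  if (!is.numeric(x) || any(x <= 0)) stop("`x` must be strictly positive.")
  w <- params$omega
  lp <- -params$gamma * base::log(params$xi) - base::log(2) -
    log_bessel_k(params$gamma, w) +
    (params$gamma - 1) * base::log(x) -
    (w / 2) * (x / params$xi + params$xi / x)
  if (log) lp else exp(lp)
}

#' GIG raw moments
#'
#' \eqn{E(\nu^k) = \xi^k K_{\gamma+k}(\varpi) / K_\gamma(\varpi)}; in
#' particular \eqn{E(\nu) = \xi R_\gamma(\varpi)}.
#'
#' @param params A [gig_params()] object.
#' @param k Non-negative integer moment order(s).
#' @return The raw moment(s) \eqn{E(\nu^k)}.
#' @examples
#' gig_moment(gig_params(0.5, 1, -1/2), 1) # 1, since R_{-1/2} = 1
#' @export
gig_moment <- function(params, k = 1) {
  stopifnot(inherits(params, "gig_params"))
  if (!is.numeric(k) || any(k < 0) || any(k != round(k))) {
    stop("`k` must be a non-negative integer.")
  }
  w <- params$omega
  exp(k * log(params$xi) + log_bessel_k(params$gamma + k, w) -
        log_bessel_k(params$gamma, w))
}

#' Variance of the GIG mixing variable
#'
#' \eqn{Var(\nu) = \xi^2 (K_{\gamma+2}/K_\gamma - R_\gamma^2)} evaluated at
#' \eqn{\varpi}.
#'
#' @inheritParams gig_moment
#' @return A positive scalar.
#' @export
gig_variance <- function(params) {
  gig_moment(params, 2) - gig_moment(params, 1)^2
}

# One draw from the two-parameter GIG(lambda >= 0, omega) with density
# proportional to y^{lambda-1} exp(-omega (y + 1/y) / 2), by Devroye's (2014)
# uniformly fast rejection method on the log scale.
rgig_devroye1 <- function(lambda, omega) {
  alpha <- sqrt(omega^2 + lambda^2) - lambda
  psi <- function(z) -alpha * (cosh(z) - 1) - lambda * (exp(z) - z - 1)
  dpsi <- function(z) -alpha * sinh(z) - lambda * (exp(z) - 1)
  v <- -psi(1)
  t <- if (v >= 0.5 && v <= 2) 1
  else if (v > 2) sqrt(2 / (alpha + lambda))
  else log(4 / (alpha + 2 * lambda))
  v <- -psi(-1)
  s <- if (v >= 0.5 && v <= 2) 1
  else if (v > 2) sqrt(4 / (alpha * cosh(1) + lambda))
  else min(1 / lambda, log(1 + 1 / alpha + sqrt(1 / alpha^2 + 2 / alpha)))
  eta <- -psi(t); zeta <- -dpsi(t); theta <- -psi(-s); xi_ <- dpsi(-s)
  p <- 1 / xi_; r <- 1 / zeta
  td <- t - r * eta; sd_ <- s - p * theta; q <- td + sd_
  repeat {
    u <- stats::runif(1); v <- stats::runif(1); w <- stats::runif(1)
    z <- if (u < q / (p + q + r)) {
      -sd_ + q * v
    } else if (u < (q + r) / (p + q + r)) {
      td - r * log(v)
    } else {
      -sd_ + p * log(v)
    }
    chi <- if (z >= -sd_ && z <= td) 1
    else if (z > td) exp(-eta - zeta * (z - t))
    else exp(-theta + xi_ * (z + s))
    if (w * chi <= exp(psi(z))) break
  }
  exp(z) * (lambda / omega + sqrt(1 + (lambda / omega)^2))
}

# Vectorized inverse-Gaussian draws IG(mu, shape) (Michael, Schucany & Haas).
rinvgauss_vec <- function(n, mu, shape) {
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * shape) -
    (mu / (2 * shape)) * sqrt(4 * mu * shape * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Sample from the GIG mixing distribution
#'
#' For the half-integer order \eqn{\gamma = -1/2} the distribution is exactly
#' inverse Gaussian with mean \eqn{\xi} and shape \eqn{\varpi\xi}, sampled by
#' the Michael-Schucany-Haas transform. For any other order a Devroye-type
#' rejection sampler is used (negative orders via the reciprocal identity
#' \eqn{1/\nu \sim} GIG with order \eqn{-\gamma} and swapped classical
#' parameters).
#'
#' @param n Number of draws.
#' @param params A [gig_params()] object.
#' @param seed Optional integer; if supplied the draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return A vector of `n` positive draws.
#' @examples
#' mean(rgig(1e4, gig_params(0.5, 1, -1/2), seed = 1)) # close to 1
#' @export
rgig <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "gig_params"), is.numeric(n), n >= 1)
  n <- as.integer(n)
  if (!is.null(seed)) withr::local_seed(seed)
  w <- params$omega
  if (params$gamma == -1/2) {
    # GIG(-1/2, a = w/xi, b = w*xi) is IG(mu = xi, shape = w*xi)
    return(rinvgauss_vec(n, params$xi, w * params$xi))
  }
  lam <- params$gamma
  swap <- lam < 0
  if (swap) lam <- -lam
  draws <- vapply(seq_len(n), function(i) rgig_devroye1(lam, w), numeric(1))
  if (swap) draws <- 1 / draws
  # rescale two-parameter draws to the (a = w/xi, b = w*xi) scale: sqrt(b/a) = xi
  draws * params$xi
}
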