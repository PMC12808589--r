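#' Chi-square critical value
#'
#' The \eqn{(1-\alpha)} quantile of the chi-square distribution, used as the
#' rejection threshold of the simultaneous likelihood-ratio test.
#'
#' @param df Positive integer degrees of freedom.
#' @param alpha Significance level in (0, 1).
#' @return The critical value.
#' @examples
#' chi2_critical(12, 0.05) # 21.026
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (!is.numeric(df) || any(df < 1) || any(df != round(df))) {
    stop("`df` must be a positive integer.")
  }
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie strictly inside (0, 1).")
  }
  stats::qchisq(1 - alpha, df = df)
}

#' Intercepts-only (null) fit
#'
#' Fits the restricted mixed model with every slope constrained to zero
#' (intercepts and the dispersion parameters \eqn{\tau,\xi} stay free,
#' \eqn{\gamma} fixed as in the full model). Convenience wrapper around
#' [fit_mcpgigr()] used by [mlrt()].
#'
#' @inheritParams fit_mcpgigr
#' @return A `mcpgigr_fit`.
#' @export
fit_mcpgigr_null <- function(panel, gamma = -1/2, tol = 1e-7, max_iter = 500L) {
  fit_mcpgigr(panel, gamma = gamma, tol = tol, max_iter = max_iter,
              intercept_only = TRUE)
}

#' Simultaneous likelihood-ratio test (MLRT)
#'
#' Tests \eqn{H_0}: all slope coefficients are zero, via
#' \eqn{G^2 = 2(\ln L(\hat\Omega) - \ln L(\hat\omega))}, referred to a
#' chi-square with \eqn{p \cdot m} degrees of freedom (one per tested slope;
#' intercepts and dispersion parameters are free under both hypotheses).
#'
#' @param full A converged full-model fit.
#' @param null The matching intercepts-only fit; fitted automatically when
#'   omitted.
#' @param alpha Significance level.
#' @return A list of class `mcpgigr_mlrt`: `statistic`, `df`, `p_value`,
#'   `critical_value`, `alpha`, `reject`, plus both log-likelihoods.
#' @export
mlrt <- function(full, null = NULL, alpha = 0.05) {
  stopifnot(inherits(full, "mcpgigr_fit"))
  if (full$intercept_only) stop("`full` is an intercepts-only fit.")
  if (is.null(null)) {
    null <- if (full$model == "MCPGIGR") {
      fit_mcpgigr_null(full$panel, gamma = full$gamma)
    } else {
      fit_mpr(full$panel, intercept_only = TRUE)
    }
  }
  stopifnot(inherits(null, "mcpgigr_fit"))
  if (!null$intercept_only) stop("`null` must be an intercepts-only fit.")
  if (!isTRUE(all.equal(dim(null$panel$data), dim(full$panel$data)))) {
    stop("Full and null fits must come from the same panel.")
  }
  g2 <- 2 * (full$loglik - null$loglik)
  if (g2 < -1e-6) {
    stop("Negative likelihood-ratio statistic (", format(g2),
         "): one of the optimizations failed.")
  }
  if (g2 < 0) {
    warning("Small negative G^2 clipped to 0.")
    g2 <- 0
  }
  df <- full$p * full$m
  structure(
    list(statistic = g2, df = df,
         p_value = stats::pchisq(g2, df, lower.tail = FALSE),
         critical_value = chi2_critical(df, alpha), alpha = alpha,
         reject = g2 > chi2_critical(df, alpha),
         loglik_full = full$loglik, loglik_null = null$loglik),
    class = "mcpgigr_mlrt"
  )
}

#' @export
print.mcpgigr_mlrt <- function(x, ...) {
  cat(sprintf(
    "Simultaneous LR test: G^2 = %.4f on %d df, p = %.4g (critical %.3f at alpha = %g) -> %s\n",
    x$statistic, x$df, x$p_value, x$critical_value, x$alpha,
    if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Per-coefficient Wald Z tests
#'
#' \eqn{Z = \hat\beta_{jk} / SE(\hat\beta_{jk})} referred to the standard
#' normal, with two-sided p-values and a decision at level `alpha`. By
#' default only slope coefficients are tested (intercepts are nuisance
#' location parameters).
#'
#' @param fit A converged fit.
#' @param alpha Significance level for the decision column.
#' @param slopes_only Drop intercept rows?
#' @return A tibble: `response`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `significant`.
#' @export
wald_tests <- function(fit, alpha = 0.05, slopes_only = TRUE) {
  stopifnot(inherits(fit, "mcpgigr_fit"))
  est <- as.vector(fit$beta)
  se <- as.vector(fit$se_beta)
  k <- nrow(fit$beta)
  out <- tibble::tibble(
    response = rep(colnames(fit$beta), each = k),
    term = rep(rownames(fit$beta), fit$m),
    estimate = est,
    std.error = se
  )
  if (slopes_only) out <- out[out$term != "(Intercept)", , drop = FALSE]
  if (any(!is.finite(out$std.error) | out$std.error <= 0)) {
    bad <- which(!is.finite(out$std.error) | out$std.error <= 0)[1]
    stop("Invalid standard error for coefficient ",
         out$response[bad], ":", out$term[bad])
  }
  out$statistic <- out$estimate / out$std.error
  out$p.value <- 2 * stats::pnorm(-abs(out$statistic))
  out$significant <- out$p.value < alpha
  out
}

#' Small-sample-corrected Akaike criterion
#'
#' \eqn{AICc = -2\ln L + 2P + 2P(P+1)/(n - P - 1)} where P is the total
#' number of freely estimated parameters (\eqn{m(p+1)+2} for the mixed model
#' with fixed \eqn{\gamma}; \eqn{m(p+1)} for the Poisson baseline) and n the
#' number of units. Lower is better.
#'
#' @param fit A converged fit (or pass `loglik`, `n_params`, `n` directly).
#' @param n Override the sample size (defaults to the fit's).
#' @return The AICc value.
#' @examples
#' aicc_value(loglik = -100, n_params = 2, n = 300) # 204.0404
#' @export
aicc <- function(fit, n = NULL) {
  stopifnot(inherits(fit, "mcpgigr_fit"))
  aicc_value(fit$loglik, fit$n_params, if (is.null(n)) fit$n else n)
}

#' @rdname aicc
#' @param loglik Maximized log-likelihood.
#' @param n_params Total count of freely estimated parameters.
#' @export
aicc_value <- function(loglik, n_params, n) {
  if (n <= n_params + 1) {
    stop("AICc undefined: n must exceed the parameter count + 1.")
  }
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n - n_params - 1)
}

# ---------------------------------------------------------------------------
# broom-style and plotting methods

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model
#'
#' One row per estimated parameter (coefficients plus, for the mixed model,
#' the natural-scale dispersion parameters), with Wald statistics.
#'
#' @param x A `mcpgigr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `response`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy mcpgigr_fit
#' @export
tidy.mcpgigr_fit <- function(x, ...) {
  out <- wald_tests(x, slopes_only = FALSE)
  out$significant <- NULL
  if (x$model == "MCPGIGR") {
    disp <- tibble::tibble(
      response = NA_character_,
      term = c("tau", "xi"),
      estimate = c(x$tau, x$xi),
      std.error = c(x$se_tau, x$se_xi),
      statistic = NA_real_,
      p.value = NA_real_
    )
    out <- dplyr::bind_rows(out, disp)
  }
  out
}

#' Glance at a fitted model
#'
#' @param x A `mcpgigr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `gamma`, `logLik`, `AICc`, `nobs`,
#'   `n_params`, `iterations`, `converged`.
#' @method glance mcpgigr_fit
#' @export
glance.mcpgigr_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, gamma = x$gamma, logLik = x$loglik, AICc = aicc(x),
    nobs = x$n, n_params = x$n_params, iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
logLik.mcpgigr_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Plot the optimization trace of a fit
#'
#' Log-likelihood (monotone by the line-search contract) and gradient norm
#' against the BHHH iteration.
#'
#' @param object A `mcpgigr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mcpgigr_fit
#' @export
autoplot.mcpgigr_fit <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace, c("loglik", "grad_norm"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("%s BHHH trace (%d iterations)", object$model,
                      object$iterations),
      x = "iteration", y = NULL
    )
}
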