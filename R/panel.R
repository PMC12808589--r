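#' Construct a validated multivariate count panel
#'
#' The unit of model fitting: for each of n observational units, m
#' non-negative integer responses (the first, "shock", component plays the
#' role of \eqn{Y_1} in the common-shock construction), m paired positive
#' exposures, and p predictors. The common-shock support law
#' \eqn{y_{ij} \ge y_{i1}} is checked at construction.
#'
#' @param data A data frame with one row per unit.
#' @param responses Character vector (length m >= 2) of response column
#'   names, in component order.
#' @param predictors Character vector (length p >= 1) of predictor column
#'   names (no intercept column; an intercept is always added when fitting).
#' @param exposures Optional character vector of exposure column names paired
#'   with `responses`; `NULL` means all exposures are 1.
#' @param shock Name of the response column acting as the shock component
#'   \eqn{Y_1}; defaults to the first entry of `responses` and is moved to the
#'   front.
#' @param id Optional name of a unit-identifier column.
#' @param on_violation What to do with rows violating the support law
#'   \eqn{y_j \ge y_1}: `"error"` (default) or `"drop"` (warn and remove).
#' @return A `count_panel` object: list with the cleaned tibble and the
#'   resolved column roles, plus dimensions `n`, `m`, `p`.
#' @examples
#' d <- tibble::tibble(y1 = c(0, 1), y2 = c(2, 1), x1 = c(0.3, -1))
#' count_panel(d, responses = c("y1", "y2"), predictors = "x1")
#' @export
count_panel <- function(data, responses, predictors, exposures = NULL,
                        shock = responses[1], id = NULL,
                        on_violation = c("error", "drop")) {
  on_violation <- match.arg(on_violation)
  data <- tibble::as_tibble(data)
  if (length(responses) < 2) stop("Need at least two response columns.")
  if (anyDuplicated(c(responses, predictors, exposures, id))) {
    stop("Column roles must not repeat a column.")
  }
  needed <- c(responses, predictors, exposures, id)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("Missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!shock %in% responses) stop("`shock` must be one of `responses`.")
  responses <- c(shock, setdiff(responses, shock))

  for (cl in c(responses, predictors, exposures)) {
    v <- data[[cl]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("Column `", cl, "` must be numeric with no missing cells.")
    }
  }
  for (cl in responses) {
    v <- data[[cl]]
    bad <- which(v < 0 | v != round(v))
    if (length(bad)) {
      stop("Column `", cl, "` must hold non-negative integers; first offending row: ", bad[1])
    }
    data[[cl]] <- as.integer(round(v))
  }
  for (cl in exposures) {
    bad <- which(data[[cl]] <= 0)
    if (length(bad)) {
      stop("Exposure column `", cl, "` must be strictly positive; first offending row: ", bad[1])
    }
  }

  y <- as.matrix(data[responses])
  viol <- which(matrixStats_any_lt(y))
  if (length(viol)) {
    if (on_violation == "error") {
      stop("Support violation (y_j < y_1 for some j >= 2) in rows: ",
           paste(utils::head(viol, 10), collapse = ", "))
    }
    warning("Dropping ", length(viol), " row(s) violating the support law: ",
            paste(utils::head(viol, 10), collapse = ", "))
    data <- data[-viol, , drop = FALSE]
  }
  if (nrow(data) < 1) stop("No rows left in the panel.")

  structure(
    list(
      data = data,
      responses = responses,
      exposures = exposures,
      predictors = predictors,
      id = id,
      n = nrow(data),
      m = length(responses),
      p = length(predictors)
    ),
    class = "count_panel"
  )
}

# rows where any non-shock count falls below the shock count
matrixStats_any_lt <- function(y) {
  if (ncol(y) < 2) return(rep(FALSE, nrow(y)))
  rowSums(y[, -1, drop = FALSE] < y[, 1]) > 0
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf(
    "Count panel: %d units, %d responses (shock: %s), %d predictors%s\n",
    x$n, x$m, x$responses[1], x$p,
    if (is.null(x$exposures)) ", unit exposures" else ""
  ))
  print(utils::head(x$data, 5))
  invisible(x)
}

# internal matrix accessors -------------------------------------------------

panel_y <- function(panel) as.matrix(panel$data[panel$responses])

panel_q <- function(panel) {
  if (is.null(panel$exposures)) {
    matrix(1, panel$n, panel$m)
  } else {
    as.matrix(panel$data[panel$exposures])
  }
}

# design matrix with leading intercept column
panel_x <- function(panel, intercept_only = FALSE) {
  if (intercept_only || panel$p == 0) {
    matrix(1, panel$n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = 1, as.matrix(panel$data[panel$predictors]))
  }
}

#' Read a count panel from CSV
#'
#' Thin wrapper over [readr::read_csv()] followed by [count_panel()]
#' validation, so malformed files fail with the offending row and column
#' named.
#'
#' @param path Path to a CSV file with a header row.
#' @inheritParams count_panel
#' @param ... Further arguments passed to [count_panel()].
#' @return A `count_panel`.
#' @export
read_panel <- function(path, responses, predictors, exposures = NULL, ...) {
  if (!file.exists(path)) stop("File not found: ", path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  count_panel(data, responses = responses, predictors = predictors,
              exposures = exposures, ...)
}

#' Write a count panel to CSV
#'
#' @param panel A `count_panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "count_panel"))
  readr::write_csv(panel$data, path, progress = FALSE)
  invisible(path)
}

#' Deterministic test panels with stored generating truth
#'
#' Packages the simulation generator into small named fixtures for unit
#' tests and examples:
#' * `"small-panel"`: n = 10, the default study truth.
#' * `"null-panel"`: n = 50, all slopes exactly zero.
#' * `"overdispersed-panel"`: n = 50, strong GIG mixing (variance/mean well
#'   above 1.5 in each component).
#'
#' @param kind One of `"small-panel"`, `"null-panel"`,
#'   `"overdispersed-panel"`.
#' @param seed Integer seed; fixtures are deterministic given it.
#' @return A list with elements `panel` (a `count_panel`) and `truth` (the
#'   generating [sim_truth()] record).
#' @export
make_fixture <- function(kind = c("small-panel", "null-panel", "overdispersed-panel"),
                         seed = 1L) {
  kind <- match.arg(kind)
  cfg <- switch(
    kind,
    "small-panel" = list(n = 10L, truth = sim_truth()),
    "null-panel" = list(
      n = 50L,
      truth = sim_truth(beta = cbind(c(0, 0, 0), c(1, 0, 0)))
    ),
    "overdispersed-panel" = list(
      n = 50L,
      truth = sim_truth(beta = cbind(c(0, 0.02, 0.03), c(1.5, 0.05, 0.04)),
                        tau = 0.25, xi = 1)
    )
  )
  design <- sim_design(cfg$n, seed = seed)
  panel <- simulate_panel(design, cfg$truth, family = "mcpgig", seed = seed + 1L)
  list(panel = panel, truth = cfg$truth)
}

#' Write a coefficient report and run metadata
#'
#' Serializes a fitted model (and optionally its test report) the way the
#' field tabulates results: one CSV row per coefficient (estimate, SE, Z,
#' p-value, decision) plus a key-value metadata CSV (model, gamma, n,
#' iterations, log-likelihood, AICc, convergence, seed, package version).
#'
#' @param fit A fitted model from [fit_mcpgigr()] or [fit_mpr()].
#' @param dir Output directory (created if needed).
#' @param tests Optional test report from [mlrt()] / [wald_tests()].
#' @param seed Optional seed to record for reproducibility.
#' @param alpha Level used for the Wald decision column.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(fit, dir, tests = NULL, seed = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "mcpgigr_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  coef_path <- file.path(dir, "coefficients.csv")
  meta_path <- file.path(dir, "run_metadata.csv")
  readr::write_csv(wald_tests(fit, alpha = alpha, slopes_only = FALSE),
                   coef_path, progress = FALSE)
  g <- glance(fit)
  meta <- tibble::tibble(
    key = c("model", "gamma", "n", "n_params", "iterations", "converged",
            "loglik", "aicc", "seed", "package_version"),
    value = as.character(c(fit$model, fit$gamma, fit$n, fit$n_params,
                           fit$iterations, fit$converged, g$logLik, g$AICc,
                           if (is.null(seed)) NA else seed,
                           as.character(utils::packageVersion("mcpgigr"))))
  )
  readr::write_csv(meta, meta_path, progress = FALSE)
  paths <- c(coef_path, meta_path)
  if (!is.null(tests)) {
    test_path <- file.path(dir, "mlrt.csv")
    readr::write_csv(tibble::as_tibble(tests[c("statistic", "df", "p_value",
                                               "critical_value", "alpha",
                                               "reject")]),
                     test_path, progress = FALSE)
    paths <- c(paths, test_path)
  }
  invisible(paths)
}
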