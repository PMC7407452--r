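# Diagnostics and order selection ahead of the Bayesian ARMA-error
# regression: OLS baseline, residual autocorrelation, augmented
# Dickey-Fuller stationarity check, and AIC-ranked ARMA(p,q) grid search.

#' Ordinary least squares baseline fit
#'
#' Fits `density ~ rate` by OLS. This is the starting point of the
#' regression pipeline: its residuals feed the stationarity and
#' autocorrelation diagnostics and the ARMA order selection, and its
#' estimates centre the priors of the Bayesian fit.
#'
#' @param blocks A `block_series` (or any data frame with `rate` and a
#'   response column).
#' @param response Name of the response column (default `"density"`; a
#'   direction name such as `"C>T"` selects that per-direction density).
#' @return An object of class `"ols_fit"`: list with `intercept`, `slope`,
#'   `se` (named standard errors), `residuals` (in block order), `sigma`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_ols <- function(blocks, response = "density") {
  x <- blocks$rate
  y <- blocks[[response]]
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 blocks")
  if (sd(x) == 0) abort("constant recombination rate: singular design")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         se = c(intercept = unname(se[1]), slope = unname(se[2])),
         residuals = unname(stats::residuals(fit)),
         sigma = stats::sigma(fit), n = length(x), lm = fit,
         response = response),
    class = "ols_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(x$se)
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (%s ~ rate), n = %d\n  intercept %.6g (se %.2g), slope %.6g (se %.2g)\n",
              x$response, x$n, x$intercept, x$se[1], x$slope, x$se[2]))
  invisible(x)
}

#' Residual autocorrelation function
#'
#' Autocorrelations of a residual series for lags 0..`max_lag` (the
#' diagnostic that reveals spatial autocorrelation between neighbouring
#' blocks along the genome).
#'
#' @param residuals Numeric series in block order.
#' @param max_lag Largest lag (default 50 blocks).
#' @return A tibble with columns `lag` and `acf`; `acf[lag == 0]` is 1.
#' @export
residual_acf <- function(residuals, max_lag = 50L) {
  if (length(residuals) <= max_lag) abort("series shorter than max_lag")
  if (sd(residuals) == 0) abort("zero-variance series")
  a <- acf(residuals, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}

# Dickey-Fuller tau distribution quantiles for the constant-only (no trend)
# regression, by sample size; used to interpolate an approximate p-value.
# Rows: n = 25, 50, 100, 250, 500, Inf; columns: lower tail probabilities.
ADF_TAU_PROBS <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
ADF_TAU_N <- c(25, 50, 100, 250, 500, Inf)
ADF_TAU_TABLE <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37, 0.00, 0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60
), nrow = 6, byrow = TRUE)

#' Augmented Dickey-Fuller stationarity test
#'
#' Tests the null of a unit root in a residual series against the
#' stationary alternative, using the constant-only regression
#' `diff(y)_t = mu + gamma * y_(t-1) + sum(delta_i * diff(y)_(t-i)) + e_t`.
#' The statistic is the t-ratio on `gamma`; the p-value is interpolated
#' from the Dickey-Fuller tau table (constant case) with sample-size
#' interpolation, and clamped (with a message) outside the tabulated range.
#' Stationarity of the residuals is what licenses approximating them by an
#' ARMA model.
#'
#' @param residuals Numeric series (length >= 20).
#' @param alpha Rejection level for the stationarity verdict (default
#'   0.05).
#' @param lags Number of augmenting lag differences; default
#'   `trunc((n - 1)^(1/3))`.
#' @return An object of class `"adf_test"`: list with `statistic`,
#'   `p_value`, `stationary` (verdict `p_value < alpha`), `lags`, `n`.
#' @export
adf_stationarity <- function(residuals, alpha = 0.05, lags = NULL) {
  y <- as.numeric(residuals)
  n <- length(y)
  if (n < 20) abort("series too short for the ADF test (need >= 20)")
  if (sd(y) == 0) abort("constant series")
  k <- lags %||% trunc((n - 1)^(1 / 3))
  dy <- diff(y)
  m <- stats::embed(dy, k + 1)
  yl <- y[(k + 1):(n - 1)]
  X <- if (k > 0) cbind(yl, m[, -1, drop = FALSE]) else cbind(yl)
  fit <- lm(m[, 1] ~ X)
  stat <- summary(fit)$coefficients["Xyl", "t value"]

  # Interpolate quantiles over sample size, then p over the tau quantiles.
  wrow <- vapply(seq_along(ADF_TAU_PROBS), function(j) {
    stats::approx(ADF_TAU_N[-6], ADF_TAU_TABLE[-6, j], xout = min(n, 500),
                  rule = 2)$y
  }, numeric(1))
  if (n > 500) wrow <- ADF_TAU_TABLE[6, ]
  if (stat <= min(wrow)) {
    p <- ADF_TAU_PROBS[1]
    inform("ADF p-value smaller than tabulated range; reporting 0.01")
  } else if (stat >= max(wrow)) {
    p <- ADF_TAU_PROBS[length(ADF_TAU_PROBS)]
    inform("ADF p-value larger than tabulated range; reporting 0.99")
  } else {
    p <- stats::approx(wrow, ADF_TAU_PROBS, xout = stat)$y
  }
  structure(list(statistic = unname(stat), p_value = p,
                 stationary = p < alpha, lags = k, n = n, alpha = alpha),
            class = "adf_test")
}

#' @export
print.adf_test <- function(x, ...) {
  cat(sprintf("ADF test: tau = %.3f, p ~ %.3f (%d lags, n = %d) -> %s\n",
              x$statistic, x$p_value, x$lags, x$n,
              if (x$stationary) "stationary" else "unit root not rejected"))
  invisible(x)
}

#' Select an ARMA order for the residuals by AIC
#'
#' Fits ARMA(p, q) models over the grid `1 <= p <= p_max`,
#' `0 <= q <= q_max` to a (stationary) residual series and ranks converged
#' fits by AIC. `rank = 2` requests the second-lowest-AIC model, the
#' fallback used when the best-ranked order destabilises the subsequent
#' MCMC.
#'
#' @param residuals Numeric residual series.
#' @param p_max,q_max Grid bounds (defaults 10 and 4).
#' @param rank Which AIC rank to select (default 1).
#' @return An object of class `"arma_order_selection"`: list with `grid`
#'   (tibble of `p`, `q`, `aic`, `converged`), `chosen` (`c(p, q)`) and
#'   `rank_used`.
#' @export
select_arma_order <- function(residuals, p_max = 10L, q_max = 4L,
                              rank = 1L) {
  if (p_max < 1) abort("p_max must be >= 1")
  grid <- tidyr::expand_grid(p = seq_len(p_max), q = 0:q_max)
  fits <- purrr::pmap_dfr(grid, function(p, q) {
    aic <- tryCatch({
      f <- suppressWarnings(
        arima(residuals, order = c(p, 0L, q), include.mean = FALSE,
              method = "CSS-ML")
      )
      if (!is.finite(f$aic) || (!is.null(f$code) && f$code != 0)) NA_real_
      else f$aic
    }, error = function(e) NA_real_)
    tibble::tibble(p = p, q = q, aic = aic, converged = is.finite(aic))
  })
  ok <- fits[fits$converged, , drop = FALSE]
  if (!nrow(ok)) abort("no ARMA model in the grid converged")
  ok <- ok[order(ok$aic), , drop = FALSE]
  if (rank > nrow(ok)) abort("requested rank exceeds number of converged fits")
  structure(
    list(grid = fits, chosen = c(p = ok$p[rank], q = ok$q[rank]),
         rank_used = as.integer(rank)),
    class = "arma_order_selection"
  )
}

# The order at a given AIC rank from an existing selection.
order_at_rank <- function(selection, rank) {
  ok <- selection$grid[selection$grid$converged, , drop = FALSE]
  ok <- ok[order(ok$aic), , drop = FALSE]
  if (rank > nrow(ok)) return(NULL)
  c(p = ok$p[rank], q = ok$q[rank])
}

#' @exportS3Method generics::tidy
tidy.arma_order_selection <- function(x, ...) x$grid

#' @export
print.arma_order_selection <- function(x, ...) {
  cat(sprintf("ARMA order selection: chosen (p, q) = (%d, %d) at AIC rank %d; %d/%d grid fits converged\n",
              x$chosen["p"], x$chosen["q"], x$rank_used,
              sum(x$grid$converged), nrow(x$grid)))
  invisible(x)
}
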