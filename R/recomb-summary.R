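# Derived recombination statistics: per-draw computation of the variance in
# SNV density due to recombination, R^2, the proportion of SNVs attributed
# to recombination, and the expected number of mutations per crossover.

#' Summarise a recombination regression posterior
#'
#' For every posterior draw, computes the regression residuals
#' `density - (alpha + beta * rate)`, and from them: the variance in SNV
#' density due to recombination `sigma2_rec = Var(density) - mean(resid^2)`
#' (negative when the fit is worse than a zero-slope line - reported
#' as-is), `R2 = sigma2_rec / Var(density)`, the proportion of SNVs
#' attributable to recombination `rho_hat = (m_bar - alpha) / m_bar`, and
#' `mutations_per_crossover = rho_hat * mu / xover`. The slope is also
#' converted to per-centimorgan units via the mean genetic length per block
#' and to mutation-rate units via `mu / m_bar`. `prob_slope_le_0` is the
#' fraction of draws with `beta <= 0`.
#'
#' @param post An `arma_regression` fit (needs >= 1000 retained draws in
#'   total).
#' @param mu Point mutation rate per bp per generation (default 1.19e-8).
#' @param xover Crossover rate per bp per generation (default 1.16e-8).
#' @param mean_cM_per_block Mean genetic length of a block in centimorgans
#'   (default 0.0116): one standardized rate unit corresponds to this many
#'   cM per block.
#' @param m_bar `"observed"` (default): mean SNV density over blocks not
#'   imputed by LOCF; `"series"`: mean over the full fitted series.
#' @return An object of class `"recomb_summary"`: list with `stats` (a
#'   tibble of posterior means and 95% credibility limits per quantity),
#'   `prob_slope_le_0`, `m_bar`, the per-draw tibble `draws`, and the
#'   constants used.
#' @export
summarize_recombination <- function(post,
                                    mu = 1.19e-8,
                                    xover = 1.16e-8,
                                    mean_cM_per_block = 0.0116,
                                    m_bar = c("observed", "series")) {
  stopifnot(inherits(post, "arma_regression"))
  m_bar <- match.arg(m_bar)
  if (nrow(post$draws) < 1000) abort("need at least 1000 posterior draws")
  mbar <- if (m_bar == "observed") post$m_bar_observed else post$m_bar_series
  if (!is.finite(mbar) || mbar == 0) abort("mean SNV density is zero")

  x <- post$x; y <- post$y
  a <- post$draws$alpha; b <- post$draws$beta
  # Mean squared residual per draw via sufficient statistics (exact).
  m_y <- mean(y); m_x <- mean(x); m_xy <- mean(x * y)
  m_y2 <- mean(y^2); m_x2 <- mean(x^2)
  msr <- m_y2 - 2 * a * m_y - 2 * b * m_xy + a^2 + 2 * a * b * m_x +
    b^2 * m_x2
  var_tot <- m_y2 - m_y^2

  d <- tibble::tibble(
    sigma2_rec = var_tot - msr,
    R2 = (var_tot - msr) / var_tot,
    rho_hat = (mbar - a) / mbar,
    mutations_per_crossover = (mbar - a) / mbar * mu / xover,
    slope_per_cM = b / mean_cM_per_block,
    slope_mutation_rate_per_cM = b / mean_cM_per_block * mu / mbar
  )

  qtl <- function(v) unname(quantile(v, c(0.025, 0.975)))
  stats <- purrr::map_dfr(
    c(alpha = "alpha", beta = "beta"), function(nm) {
      v <- post$draws[[nm]]
      tibble::tibble(quantity = nm, mean = mean(v),
                     lower95 = qtl(v)[1], upper95 = qtl(v)[2])
    })
  stats <- dplyr::bind_rows(stats, purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    tibble::tibble(quantity = nm, mean = mean(v),
                   lower95 = qtl(v)[1], upper95 = qtl(v)[2])
  }))

  structure(
    list(stats = stats,
         prob_slope_le_0 = mean(b <= 0),
         m_bar = mbar, m_bar_mode = m_bar, var_total = var_tot,
         draws = d,
         constants = c(mu = mu, xover = xover,
                       mean_cM_per_block = mean_cM_per_block),
         order = post$order, response = post$response %||% "density"),
    class = "recomb_summary"
  )
}

#' @exportS3Method generics::tidy
tidy.recomb_summary <- function(x, ...) x$stats

#' @exportS3Method generics::glance
glance.recomb_summary <- function(x, ...) {
  s <- function(q) x$stats$mean[x$stats$quantity == q]
  tibble::tibble(
    m_bar = x$m_bar, slope = s("beta"), intercept = s("alpha"),
    prob_slope_le_0 = x$prob_slope_le_0, sigma2_rec = s("sigma2_rec"),
    R2 = s("R2"), rho_hat = s("rho_hat"),
    mutations_per_crossover = s("mutations_per_crossover")
  )
}

#' @export
print.recomb_summary <- function(x, ...) {
  cat(sprintf(
    "Recombination summary (%s; ARMA(%d,%d) errors; m_bar = %.5g, %s)\n",
    x$response, x$order["p"], x$order["q"], x$m_bar, x$m_bar_mode))
  cat(sprintf("P(slope <= 0) = %.4f\n", x$prob_slope_le_0))
  print(x$stats, n = nrow(x$stats))
  invisible(x)
}

#' Mutations per crossover implied by a slope (naive published calculation)
#'
#' Reproduces, for comparison output, the published calculation that divides
#' a regression slope (mutations per bp per cM) by 0.01 to obtain mutation
#' events per recombination event - e.g. 0.0015 / 0.01 = 0.15. The
#' calculation implicitly attributes all recombination-associated mutations
#' to crossovers of the most recent generation, which is why it exceeds
#' direct de novo estimates by about two orders of magnitude; it is provided
#' as the contrast to the intercept-based estimate of
#' [summarize_recombination()].
#'
#' @param slope_per_cM Slope in mutations per bp per centimorgan (>= 0).
#' @return Mutations per crossover under the naive reading.
#' @export
slope_implied_mutations_per_crossover_naive <- function(slope_per_cM) {
  stopifnot(all(slope_per_cM >= 0))
  slope_per_cM / 0.01
}

#' Proportion of mutations directly caused by crossovers
#'
#' The arithmetic linking a per-crossover mutation probability to the
#' proportion of the mutation rate directly caused by crossovers: given the
#' probability `rho` that a crossover causes a mutation, the average point
#' mutation rate `y` and the average crossover rate `x` (both per bp per
#' generation), the proportion is `rho * x / y` (e.g. 0.29% per crossover
#' with x = 1.16e-8 and y = 1.19e-8 gives 0.28% of mutations).
#'
#' @param rho_per_crossover Probability that a crossover causes a mutation.
#' @param xover Crossover rate per bp per generation.
#' @param mu Point mutation rate per bp per generation.
#' @return The proportion of mutations directly caused by crossovers.
#' @export
crossover_mutation_proportion <- function(rho_per_crossover,
                                          xover = 1.16e-8,
                                          mu = 1.19e-8) {
  rho_per_crossover * xover / mu
}

#' Run the full recombination-regression pipeline on one block series
#'
#' Convenience driver: OLS baseline, residual ACF, ADF stationarity check,
#' AIC order selection, joint Bayesian ARMA-error fit (with AIC-rank
#' fallback on diagnostic failure), and the derived-statistic summary.
#'
#' @inheritParams fit_bayes_arma_regression
#' @inheritParams summarize_recombination
#' @param p_max,q_max ARMA order-selection grid bounds.
#' @param adf_alpha Level for the stationarity verdict.
#' @return A list of class `"recomb_analysis"` with elements `ols`, `acf`,
#'   `adf`, `selection`, `posterior`, `summary`.
#' @export
analyze_recombination <- function(blocks, response = "density",
                                  p_max = 10L, q_max = 4L,
                                  chains = 4L, draws = 2000L, tune = 1000L,
                                  seed = 1L, adf_alpha = 0.05,
                                  mu = 1.19e-8, xover = 1.16e-8,
                                  mean_cM_per_block = 0.0116,
                                  rate_error_sd = NULL,
                                  m_bar = c("observed", "series")) {
  ols <- fit_ols(blocks, response = response)
  ac <- residual_acf(ols$residuals,
                     max_lag = min(50L, length(ols$residuals) - 1L))
  adf <- adf_stationarity(ols$residuals, alpha = adf_alpha)
  if (!adf$stationary) {
    warn("ADF test did not reject a unit root in the OLS residuals; the ARMA approximation may be inappropriate")
  }
  sel <- select_arma_order(ols$residuals, p_max = p_max, q_max = q_max)
  post <- fit_bayes_arma_regression(blocks, sel, response = response,
                                    chains = chains, draws = draws,
                                    tune = tune, seed = seed,
                                    rate_error_sd = rate_error_sd)
  summ <- summarize_recombination(post, mu = mu, xover = xover,
                                  mean_cM_per_block = mean_cM_per_block,
                                  m_bar = m_bar)
  structure(list(ols = ols, acf = ac, adf = adf, selection = sel,
                 posterior = post, summary = summ),
            class = "recomb_analysis")
}

#' @export
print.recomb_analysis <- function(x, ...) {
  print(x$adf)
  print(x$selection)
  print(x$summary)
  invisible(x)
}
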