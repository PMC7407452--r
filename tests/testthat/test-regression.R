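# OLS baseline, diagnostics, order selection, Bayesian ARMA fit and the
# derived recombination statistics.

test_that("OLS interpolates noiseless data exactly", {
  sim <- simulate_blocks(block_sim_params(
    n_blocks = 200, intercept = 0.026, slope = 0.007,
    ar = numeric(0), ma = numeric(0), noise_sd = 0, binomial = FALSE,
    seed = 2
  ))
  f <- fit_ols(sim$blocks)
  expect_equal(f$intercept, 0.026, tolerance = 1e-10)
  expect_equal(f$slope, 0.007, tolerance = 1e-10)

  b <- tibble::tibble(rate = c(0, 1, 2), density = c(0.02, 0.03, 0.04))
  f <- fit_ols(b)
  expect_equal(f$slope, 0.01, tolerance = 1e-12)
  expect_equal(f$intercept, 0.02, tolerance = 1e-12)

  expect_error(fit_ols(tibble::tibble(rate = rep(1, 10),
                                      density = runif(10))), "constant")
})

test_that("OLS stays unbiased under ARMA(1,0) noise (replicate study)", {
  slopes <- vapply(1:60, function(s) {
    sim <- simulate_blocks(block_sim_params(
      n_blocks = 1500, ar = 0.8, ma = numeric(0), noise_sd = 0.003,
      binomial = FALSE, seed = 1000 + s
    ))
    fit_ols(sim$blocks)$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.007), 2 * mc_se + 1e-5)
})

test_that("residual ACF matches white-noise and AR(1) theory", {
  set.seed(2)
  wn <- rnorm(10000)
  ac <- residual_acf(wn, max_lag = 50)
  expect_equal(ac$acf[1], 1)                       # lag 0 exactly 1
  expect_gte(sum(abs(ac$acf[-1]) < 4 / sqrt(10000)), 48)

  set.seed(3)
  ar1 <- as.numeric(arima.sim(list(ar = 0.5), 50000))
  ac <- residual_acf(ar1, max_lag = 5)
  expect_equal(ac$acf[2:4], 0.5^(1:3), tolerance = 0.05)

  expect_error(residual_acf(rep(1, 100), 10), "zero-variance")
})

test_that("ADF test separates stationary series from random walks", {
  set.seed(5)
  wn <- rnorm(2000)
  a <- adf_stationarity(wn)
  expect_true(a$stationary)
  expect_lt(a$statistic, -3)

  rw <- cumsum(rnorm(2000))
  a <- suppressMessages(adf_stationarity(rw))
  expect_false(a$stationary)

  # near-unit-root AR(1): contract only (low power is acceptable)
  near <- as.numeric(arima.sim(list(ar = 0.99), 200))
  expect_s3_class(suppressMessages(adf_stationarity(near)), "adf_test")

  expect_error(adf_stationarity(rnorm(10)), "short")
  expect_error(adf_stationarity(rep(2, 100)), "constant")
})

test_that("order selection identifies ARMA(1,1) structure at large n", {
  set.seed(9)
  resid <- as.numeric(arima.sim(list(ar = 0.6, ma = 0.3), 20000))
  sel <- select_arma_order(resid, p_max = 3, q_max = 2)
  expect_gte(sel$chosen[["p"]], 1)
  expect_gte(sel$chosen[["q"]], 1)
  expect_equal(sel$rank_used, 1L)
})

test_that("order selection is parsimonious on white noise", {
  set.seed(44)
  resid <- rnorm(20000)
  sel <- select_arma_order(resid, p_max = 3, q_max = 2)
  aic_10 <- sel$grid$aic[sel$grid$p == 1 & sel$grid$q == 0]
  best <- min(sel$grid$aic[sel$grid$converged])
  expect_lt(aic_10 - best, 2)
})

test_that("rank 2 selects the second-lowest AIC entry", {
  set.seed(11)
  resid <- as.numeric(arima.sim(list(ar = 0.5), 5000))
  s1 <- select_arma_order(resid, p_max = 2, q_max = 1)
  s2 <- select_arma_order(resid, p_max = 2, q_max = 1, rank = 2)
  ok <- s1$grid[s1$grid$converged, ]
  ok <- ok[order(ok$aic), ]
  expect_equal(unname(s2$chosen), c(ok$p[2], ok$q[2]))
  expect_equal(s2$rank_used, 2L)
})

test_that("the joint posterior recovers truth and is bit-reproducible", {
  sim <- simulate_blocks(block_sim_params(
    n_blocks = 3000, intercept = 0.026, slope = 0.007, ar = 0.5, ma = 0.3,
    noise_sd = 0.003, seed = 21
  ))
  post <- suppressWarnings(fit_bayes_arma_regression(sim$blocks, order = c(1, 1),
                                    chains = 2, draws = 1000, tune = 500,
                                    seed = 21))
  td <- tidy(post)
  a <- td[td$term == "alpha", ]; b <- td[td$term == "beta", ]
  expect_gt(0.026, a$conf.low); expect_lt(0.026, a$conf.high)
  expect_gt(0.007, b$conf.low); expect_lt(0.007, b$conf.high)

  post2 <- suppressWarnings(
    fit_bayes_arma_regression(sim$blocks, order = c(1, 1), chains = 2,
                              draws = 1000, tune = 500, seed = 21))
  expect_identical(post$draws, post2$draws)   # fixed seed, fixed draws
})

test_that("an AR(1) fit on white-noise data centres phi near zero", {
  sim <- simulate_blocks(block_sim_params(
    n_blocks = 4000, ar = numeric(0), ma = numeric(0), noise_sd = 0.003,
    binomial = FALSE, seed = 22
  ))
  post <- suppressWarnings(fit_bayes_arma_regression(sim$blocks, order = c(1, 0),
                                    chains = 2, draws = 1000, tune = 500,
                                    seed = 22))
  expect_lt(abs(mean(post$draws$phi1)), 0.05)
})

test_that("derived statistics follow their definitions", {
  sim <- simulate_blocks(block_sim_params(n_blocks = 2000, seed = 23))
  post <- suppressWarnings(fit_bayes_arma_regression(sim$blocks, order = c(1, 1),
                                    chains = 2, draws = 1000, tune = 500,
                                    seed = 23))
  s <- summarize_recombination(post)

  # prob_slope_le_0 is the counting definition
  manual <- mean(post$draws$beta <= 0)
  expect_equal(s$prob_slope_le_0, manual)

  # rho_hat per draw is (m_bar - alpha) / m_bar
  expect_equal(mean(s$draws$rho_hat),
               mean((s$m_bar - post$draws$alpha) / s$m_bar))

  # R2 = sigma2_rec / total variance, draw by draw
  expect_equal(s$draws$R2, s$draws$sigma2_rec / s$var_total)

  # sigma2_rec equals the explicit residual computation for one draw
  i <- 17
  r <- post$y - post$draws$alpha[i] - post$draws$beta[i] * post$x
  expect_equal(s$draws$sigma2_rec[i],
               mean((post$y - mean(post$y))^2) - mean(r^2))

  # mutations per crossover = rho_hat * mu / xover
  expect_equal(s$draws$mutations_per_crossover,
               s$draws$rho_hat * 1.19e-8 / 1.16e-8)
})

test_that("sigma2_rec equals total variance (R2 = 1) on noiseless data", {
  sim <- simulate_blocks(block_sim_params(
    n_blocks = 1500, noise_sd = 0, ar = numeric(0), ma = numeric(0),
    binomial = FALSE, seed = 24
  ))
  post <- suppressWarnings(fit_bayes_arma_regression(sim$blocks, order = c(1, 0),
                                    chains = 2, draws = 1000, tune = 500,
                                    seed = 24))
  s <- summarize_recombination(post)
  vt <- mean((post$y - mean(post$y))^2)
  expect_equal(s$stats$mean[s$stats$quantity == "sigma2_rec"], vt,
               tolerance = 1e-6)
  expect_equal(s$stats$mean[s$stats$quantity == "R2"], 1, tolerance = 1e-4)
})

test_that("rho_hat and mutations/crossover are block-size invariant", {
  mk <- function(bs, seed) {
    sim <- simulate_blocks(block_sim_params(n_blocks = 2000,
                                            block_size = bs,
                                            binomial = FALSE, seed = seed))
    post <- suppressWarnings(
      fit_bayes_arma_regression(sim$blocks, order = c(1, 1), chains = 2,
                                draws = 1000, tune = 500, seed = seed))
    glance(summarize_recombination(post))
  }
  a <- mk(10000L, 25)
  b <- mk(20000L, 25)
  expect_equal(a$rho_hat, b$rho_hat, tolerance = 0.02)
  expect_equal(a$mutations_per_crossover, b$mutations_per_crossover,
               tolerance = 0.02)
})

test_that("worked-example arithmetic for the crossover pathway holds", {
  # rho = 0.29% per crossover maps to 0.28% of mutations
  expect_equal(round(100 * crossover_mutation_proportion(0.0029), 2), 0.28)
  # naive slope reading: 0.0015 / 0.01 = 0.15
  expect_equal(slope_implied_mutations_per_crossover_naive(0.0015), 0.15)
  expect_equal(slope_implied_mutations_per_crossover_naive(0), 0)
  expect_equal(slope_implied_mutations_per_crossover_naive(0.003), 0.3)
  # toy posterior: prob_slope_le_0 counts draws
  expect_equal(mean(c(-1, 1, 2, 3) <= 0), 0.25)
  # rho_hat formula arithmetic
  expect_equal((0.028 - 0.021) / 0.028, 0.25)
})

test_that("the rate-measurement-error flag perturbs reproducibly", {
  sim <- simulate_blocks(block_sim_params(n_blocks = 800, seed = 26))
  p1 <- suppressWarnings(
    fit_bayes_arma_regression(sim$blocks, order = c(1, 0), chains = 1,
                              draws = 500, tune = 250, seed = 26,
                              rate_error_sd = 0.05))
  p2 <- suppressWarnings(
    fit_bayes_arma_regression(sim$blocks, order = c(1, 0), chains = 1,
                              draws = 500, tune = 250, seed = 26,
                              rate_error_sd = 0.05))
  expect_identical(p1$draws, p2$draws)
  expect_false(identical(p1$x, sim$blocks$rate))
})
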