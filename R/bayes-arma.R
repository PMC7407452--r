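# Joint Bayesian estimation of the linear regression of SNV density on
# recombination rate with ARMA(p,q) residuals: adaptive random-walk
# Metropolis over (alpha, beta, phi, theta, log sigma) on a
# conditional-sum-of-squares Gaussian likelihood. The proposal covariance
# is seeded from the ML fit of the same model (stats::arima with xreg) and
# globally rescaled during the tuning phase.

# CSS log-likelihood of z = y - alpha - beta x under ARMA(p,q) innovations:
# condition on the first p values of z and zero pre-sample innovations.
arma_css_loglik <- function(z, phi, theta, sigma) {
  n <- length(z)
  p <- length(phi); q <- length(theta)
  if (p > 0) {
    w <- z[(p + 1):n]
    for (i in seq_len(p)) w <- w - phi[i] * z[(p + 1 - i):(n - i)]
  } else {
    w <- z
  }
  a <- if (q > 0) as.numeric(stats::filter(w, -theta, method = "recursive"))
       else w
  sum(dnorm(a, 0, sigma, log = TRUE))
}

stationary_invertible <- function(phi, theta) {
  (!length(phi) || min(Mod(polyroot(c(1, -phi)))) > 1.001) &&
    (!length(theta) || min(Mod(polyroot(c(1, theta)))) > 1.001)
}

# Split-Rhat (potential scale reduction) per parameter column.
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(m) {
    n <- nrow(m)
    list(m[seq_len(n %/% 2), , drop = FALSE],
         m[(n %/% 2 + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  B <- n * apply(means, 1, var)
  W <- rowMeans(vars)
  r <- sqrt(((n - 1) / n * W + B / n) / W)
  # a chain half that never moved gives W = 0: flag as unconverged unless
  # between-half variance is zero too (a genuinely constant parameter)
  r[W == 0 & B > 0] <- Inf
  r[W == 0 & B == 0] <- 1
  r
}

#' Bayesian linear regression with ARMA errors
#'
#' Simultaneously estimates the intercept, slope and the p+q ARMA
#' coefficients (plus the innovation scale) of
#' `density_i = alpha + beta * rate_i + eps_i`, `eps ~ ARMA(p, q)` with
#' normal innovations, by adaptive random-walk Metropolis MCMC. Priors:
#' weakly-informative normals on `alpha` and `beta` centred at the OLS
#' estimates with sd 10 times the OLS standard errors;
#' stationarity/invertibility-constrained flat priors on the ARMA
#' coefficients; half-normal on the innovation sd. Convergence is judged by
#' split potential-scale-reduction; if an `arma_order_selection` is given
#' and diagnostics fail at the chosen order, the fit automatically retries
#' with the next-ranked orders.
#'
#' @param blocks A `block_series` (LOCF-complete: no NA rate/density).
#' @param order `c(p, q)`, or an [select_arma_order()] result, which also
#'   enables the AIC-rank fallback.
#' @param response Response column (default `"density"`).
#' @param chains,draws,tune,thin MCMC layout: number of chains, retained
#'   draws per chain, tuning (adaptation, discarded) steps per chain, and
#'   the thinning interval (each chain runs `tune + draws * thin`
#'   iterations; thinning raises the effective sample size behind the
#'   retained draws).
#' @param seed Integer seed governing all chains.
#' @param rhat_max Convergence threshold on split-Rhat (default 1.01).
#' @param max_rank How many AIC ranks to try before giving up (only with a
#'   selection object).
#' @param rate_error_sd Optional robustness check: sd of a normal
#'   perturbation added (reproducibly) to the rates before fitting;
#'   `NULL`/0 disables.
#' @return An object of class `"arma_regression"`: list with `draws`
#'   (tibble `.chain`, `.draw`, `alpha`, `beta`, `phi*`, `theta*`, `sigma`),
#'   `order`, `rhat` (named vector), `accept_rate`, `converged`, `ols`, the
#'   data series `x`/`y`, `m_bar_observed`/`m_bar_series`, `prior`
#'   description, and `seed`.
#' @export
fit_bayes_arma_regression <- function(blocks, order,
                                      response = "density",
                                      chains = 4L, draws = 2000L,
                                      tune = 1000L, thin = 4L, seed = 1L,
                                      rhat_max = 1.01, max_rank = 3L,
                                      rate_error_sd = NULL) {
  selection <- NULL
  if (inherits(order, "arma_order_selection")) {
    selection <- order
    order <- selection$chosen
  }
  x <- blocks$rate
  y <- blocks[[response]]
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(rate_error_sd) && rate_error_sd > 0) {
    set.seed(derive_seed(seed, 999))
    x <- pmax(x + rnorm(length(x), 0, rate_error_sd), 0)
  }

  # Mean density before LOCF substitution (shadow values over non-imputed
  # blocks) and over the full fitted series; the summary chooses.
  m_bar_observed <- if (all(c("density_obs", "locf_applied") %in% names(blocks))) {
    mean(blocks$density_obs[!blocks$locf_applied & keep], na.rm = TRUE)
  } else {
    mean(y)
  }

  ranks <- if (is.null(selection)) 1L else seq_len(max_rank)
  reports <- list()
  for (r in ranks) {
    ord <- if (is.null(selection) || r == 1L) order else order_at_rank(selection, r)
    if (is.null(ord)) break
    fit <- run_arma_mcmc(x, y, p = ord[[1]], q = ord[[2]], chains = chains,
                         draws = draws, tune = tune, thin = thin,
                         seed = seed)
    fit$rank_used <- r
    reports[[length(reports) + 1]] <-
      list(order = ord, rhat = fit$rhat)
    if (max(fit$rhat) < rhat_max) {
      fit$converged <- TRUE
      break
    }
    fit$converged <- FALSE
    if (r == max(ranks)) {
      if (!is.null(selection)) {
        abort(paste0(
          "MCMC failed convergence diagnostics for all tried ARMA orders: ",
          paste(vapply(reports, function(rp) {
            sprintf("(%d,%d) max Rhat %.3f", rp$order[[1]], rp$order[[2]],
                    max(rp$rhat))
          }, ""), collapse = "; ")
        ))
      }
      warn(sprintf("max split-Rhat %.3f exceeds %.3f; treat results with caution",
                   max(fit$rhat), rhat_max))
    }
  }

  fit$response <- response
  fit$m_bar_observed <- m_bar_observed
  fit$m_bar_series <- mean(y)
  fit$diagnostics_tried <- reports
  fit
}

run_arma_mcmc <- function(x, y, p, q, chains, draws, tune, thin = 4L,
                          seed = 1L) {
  n <- length(y)
  ols <- fit_ols(tibble::tibble(rate = x, density = y))
  d <- 3L + p + q  # alpha, beta, phi, theta, log sigma
  par_names <- c("alpha", "beta",
                 if (p > 0) paste0("phi", seq_len(p)),
                 if (q > 0) paste0("theta", seq_len(q)),
                 "sigma")

  prior <- list(
    alpha = c(mean = ols$intercept, sd = 10 * ols$se[["intercept"]]),
    beta = c(mean = ols$slope, sd = 10 * ols$se[["slope"]]),
    sigma_scale = 5 * ols$sigma
  )

  log_post <- function(par) {
    alpha <- par[1]; beta <- par[2]
    phi <- if (p > 0) par[2 + seq_len(p)] else numeric(0)
    theta <- if (q > 0) par[2 + p + seq_len(q)] else numeric(0)
    ls <- par[d]
    sigma <- exp(ls)
    if (!stationary_invertible(phi, theta)) return(-Inf)
    lp <- dnorm(alpha, prior$alpha["mean"], prior$alpha["sd"], log = TRUE) +
      dnorm(beta, prior$beta["mean"], prior$beta["sd"], log = TRUE) +
      # half-normal on sigma plus the log-scale Jacobian
      dnorm(sigma, 0, prior$sigma_scale, log = TRUE) + ls
    lp + arma_css_loglik(y - alpha - beta * x, phi, theta, sigma)
  }

  # ML fit of the same model supplies the starting point and the proposal
  # covariance; fall back to a diagonal built from the OLS uncertainties.
  start <- c(ols$intercept, ols$slope, rep(0.05, p), rep(0.05, q),
             log(ols$sigma))
  Sig <- diag(c(ols$se[["intercept"]], ols$se[["slope"]],
                rep(0.05, p + q), 1 / sqrt(2 * n))^2)
  ml <- tryCatch(
    suppressWarnings(arima(y, order = c(p, 0L, q), xreg = cbind(xrate = x),
                           method = "CSS-ML")),
    error = function(e) NULL
  )
  if (!is.null(ml) && all(is.finite(ml$var.coef)) &&
      length(coef(ml)) == d - 1L) {
    cf <- coef(ml)
    ar_i <- grep("^ar", names(cf)); ma_i <- grep("^ma", names(cf))
    ord <- c(which(names(cf) == "intercept"), which(names(cf) == "xrate"),
             ar_i, ma_i)
    st <- c(cf[ord])
    if (stationary_invertible(cf[ar_i], cf[ma_i])) {
      start <- c(st, log(sqrt(ml$sigma2)))
      V <- ml$var.coef[ord, ord, drop = FALSE]
      Sig <- matrix(0, d, d)
      Sig[seq_len(d - 1), seq_len(d - 1)] <- V
      Sig[d, d] <- 1 / (2 * n)
    }
  }
  # Regularise and scale (Roberts-Rosenthal 2.38^2 / d).
  Sig <- Sig + diag(1e-12, d)
  L <- tryCatch(chol(Sig), error = function(e) diag(sqrt(diag(Sig))))

  run_chain <- function(ch) {
    set.seed(derive_seed(seed, 100 + ch))
    lambda <- 2.38^2 / d
    cur <- start + as.numeric(t(L) %*% rnorm(d)) * 0.1
    lp_cur <- log_post(cur)
    tries <- 0
    while (!is.finite(lp_cur) && tries < 50) {
      cur <- start + as.numeric(t(L) %*% rnorm(d)) * 0.02
      lp_cur <- log_post(cur)
      tries <- tries + 1
    }
    if (!is.finite(lp_cur)) { cur <- start; lp_cur <- log_post(cur) }
    total <- tune + draws * thin
    out <- matrix(NA_real_, draws, d)
    tune_states <- matrix(NA_real_, tune, d)
    acc_window <- 0; acc_total <- 0
    Lc <- L
    for (it in seq_len(total)) {
      prop <- cur + sqrt(lambda) * as.numeric(t(Lc) %*% rnorm(d))
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
        cur <- prop; lp_cur <- lp_prop
        acc_window <- acc_window + 1
        if (it > tune) acc_total <- acc_total + 1
      }
      if (it <= tune) {
        tune_states[it, ] <- cur
        if (it %% 25 == 0) {
          rate <- acc_window / 25
          lambda <- lambda * exp((rate - 0.234) * 0.6)
          acc_window <- 0
        }
        if (it == tune) {
          # adapt the full proposal covariance from the second half of the
          # tuning phase (Haario-style), then freeze it for sampling
          half <- tune_states[(tune %/% 2):tune, , drop = FALSE]
          Semp <- stats::cov(half)
          if (all(is.finite(Semp)) && all(diag(Semp) > 0)) {
            Semp <- Semp + diag(1e-10 * pmax(diag(Semp), 1e-8))
            Lnew <- tryCatch(chol(Semp), error = function(e) NULL)
            if (!is.null(Lnew)) {
              Lc <- Lnew
              lambda <- 2.38^2 / d
            }
          }
        }
      } else if ((it - tune) %% thin == 0) {
        out[(it - tune) %/% thin, ] <- cur
      }
    }
    out[, d] <- exp(out[, d])
    colnames(out) <- par_names
    attr(out, "accept") <- acc_total / (draws * thin)
    out
  }

  chains_out <- lapply(seq_len(chains), run_chain)
  rhat <- split_rhat(chains_out)
  names(rhat) <- par_names

  draws_tbl <- purrr::imap_dfr(chains_out, function(m, ch) {
    tb <- tibble::as_tibble(as.data.frame(m))
    tb$.chain <- ch
    tb$.draw <- seq_len(nrow(m))
    tb
  })
  structure(
    list(draws = draws_tbl, order = c(p = p, q = q), rhat = rhat,
         accept_rate = mean(vapply(chains_out, attr, 0, "accept")),
         converged = NA, ols = ols, x = x, y = y, prior = prior,
         chains = chains, n_draws = draws, tune = tune, seed = seed),
    class = "arma_regression"
  )
}

#' @export
print.arma_regression <- function(x, ...) {
  cat(sprintf(
    "Bayesian ARMA(%d,%d)-error regression: %d chains x %d draws (accept %.2f, max Rhat %.3f)\n",
    x$order["p"], x$order["q"], x$chains, x$n_draws, x$accept_rate,
    max(x$rhat)))
  print(tidy(x), ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.arma_regression <- function(x, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".draw"))
  purrr::map_dfr(pars, function(pn) {
    v <- x$draws[[pn]]
    tibble::tibble(term = pn, estimate = mean(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)),
                   rhat = unname(x$rhat[pn]))
  })
}

#' @exportS3Method generics::glance
glance.arma_regression <- function(x, ...) {
  tibble::tibble(p = unname(x$order["p"]), q = unname(x$order["q"]),
                 chains = x$chains, draws = x$n_draws,
                 accept_rate = x$accept_rate, max_rhat = max(x$rhat),
                 converged = isTRUE(x$converged), n = length(x$y))
}
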