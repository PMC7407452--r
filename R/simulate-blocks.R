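# Block-series simulator: the generative inverse of the regression model.
# density_i = intercept + slope * rate_i + eps_i, with eps an ARMA(p,q)
# process, and (optionally) binomial resampling of SNV counts around the
# model density, matching the binomial nature of count data that plain OLS
# assumptions ignore.

#' Block-series simulation parameters
#'
#' Bundles and validates the parameters of the generative model behind the
#' recombination regression: a linear rate-to-density relationship with
#' ARMA-correlated residuals over 10-kb-style blocks, binomial SNV counts,
#' a hotspot-laden recombination-rate distribution and run-structured
#' missingness.
#'
#' @param n_blocks Number of blocks.
#' @param intercept SNV density at zero recombination (density units).
#' @param slope Change in SNV density per standardized rate unit.
#' @param ar,ma Numeric vectors of AR and MA coefficients (may be empty).
#'   The AR polynomial must be stationary (roots outside the unit circle)
#'   and the MA polynomial invertible.
#' @param noise_sd Innovation standard deviation of the ARMA residual
#'   process, in density units.
#' @param rate_shape Gamma shape of the background standardized-rate
#'   distribution (scale free: rates are re-standardized to mean 1).
#' @param hotspot_weight Probability that a block is a recombination
#'   hotspot.
#' @param hotspot_mult Rate multiplier applied to hotspot blocks.
#' @param missing_fraction Expected fraction of blocks flagged missing
#'   (deCODE-unsequenced analogue), in `[0, 1)`.
#' @param block_size Block length in bp.
#' @param binomial If `TRUE` (default), SNV counts are drawn
#'   `Binomial(block_size, density)` and re-normalised to densities; if
#'   `FALSE` the model densities are returned exactly (used for noiseless
#'   degenerate checks).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `"block_sim_params"`.
#' @export
block_sim_params <- function(n_blocks = 5000,
                             intercept = 0.026,
                             slope = 0.007,
                             ar = 0.5,
                             ma = 0.3,
                             noise_sd = 0.003,
                             rate_shape = 0.6,
                             hotspot_weight = 0.02,
                             hotspot_mult = 10,
                             missing_fraction = 0,
                             block_size = 10000L,
                             binomial = TRUE,
                             seed = 1L) {
  ar <- as.numeric(ar); ma <- as.numeric(ma)
  if (length(ar) && min(Mod(polyroot(c(1, -ar)))) <= 1) {
    abort("AR polynomial is not stationary (root inside the unit circle)")
  }
  if (length(ma) && min(Mod(polyroot(c(1, ma)))) <= 1) {
    abort("MA polynomial is not invertible")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must lie in [0, 1)")
  }
  if (intercept < 0 || intercept > 1) abort("intercept must lie in [0, 1]")
  structure(
    list(n_blocks = as.integer(n_blocks), intercept = intercept,
         slope = slope, ar = ar, ma = ma, noise_sd = noise_sd,
         rate_shape = rate_shape, hotspot_weight = hotspot_weight,
         hotspot_mult = hotspot_mult, missing_fraction = missing_fraction,
         block_size = as.integer(block_size), binomial = binomial,
         seed = as.integer(seed)),
    class = "block_sim_params"
  )
}

#' Simulate a block series with known ground truth
#'
#' Draws standardized recombination rates from a gamma background plus a
#' hotspot component (re-standardized to mean 1, as deCODE rates are
#' normalised by the genome-wide mean genetic length), builds densities
#' `intercept + slope * rate + eps` with ARMA(p,q) residuals, resamples
#' binomial SNV counts per block, and optionally flags run-structured
#' missing blocks. The truth record retains every parameter, the realized
#' residuals and the pre-noise densities for recovery tests.
#'
#' @param params A [block_sim_params()] object.
#' @return A list with `blocks` (a `block_series` tibble with shadow columns
#'   `rate_obs`, `density_obs`) and `truth` (list of generative parameters,
#'   realized residuals `eps` and model densities `density_true`).
#' @export
simulate_blocks <- function(params = block_sim_params()) {
  stopifnot(inherits(params, "block_sim_params"))
  p <- params
  n <- p$n_blocks
  set.seed(derive_seed(p$seed, 1))

  rate <- rgamma(n, shape = p$rate_shape, scale = 1)
  hot <- runif(n) < p$hotspot_weight
  rate[hot] <- rate[hot] * p$hotspot_mult
  rate <- rate / mean(rate)

  if (p$noise_sd > 0) {
    if (length(p$ar) || length(p$ma)) {
      model <- list()
      if (length(p$ar)) model$ar <- p$ar
      if (length(p$ma)) model$ma <- p$ma
      eps <- as.numeric(arima.sim(model = model, n = n, sd = p$noise_sd))
    } else {
      eps <- rnorm(n, 0, p$noise_sd)
    }
  } else {
    eps <- numeric(n)
  }

  density_true <- p$intercept + p$slope * rate + eps
  if (any(density_true < 0 | density_true > 1)) {
    abort("simulated density outside [0, 1]; narrow the parameter ranges")
  }
  density <- if (p$binomial) {
    rbinom(n, p$block_size, density_true) / p$block_size
  } else {
    density_true
  }

  blocks <- structure(
    tibble::tibble(
      chrom = "sim1",
      start = (seq_len(n) - 1) * p$block_size,
      rate = rate,
      density = density,
      missing = FALSE,
      excluded = FALSE,
      locf_applied = FALSE,
      rate_obs = rate,
      density_obs = density
    ),
    block_size = p$block_size,
    class = c("block_series", class(tibble::tibble()))
  )
  if (p$missing_fraction > 0) {
    blocks <- inject_missing(blocks, p$missing_fraction,
                             seed = derive_seed(p$seed, 2))
  }
  truth <- list(params = p, eps = eps, density_true = density_true,
                rate = rate)
  list(blocks = blocks, truth = truth)
}

#' Flag runs of blocks as missing
#'
#' Emulates deCODE-unsequenced regions: missingness arrives in runs
#' (geometric run length, default mean 2) because the downstream exclusion
#' rule targets successive excluded blocks. Each block independently starts
#' a run with probability `fraction / mean_run`, so the expected flagged
#' fraction is `fraction`. Original rates and densities are kept in the
#' shadow columns `rate_obs` / `density_obs`; flagged blocks get
#' `missing = TRUE` and `NA` observable values.
#'
#' @param blocks A `block_series` tibble.
#' @param fraction Expected missing fraction, in `[0, 1)`.
#' @param seed Integer seed.
#' @param mean_run Mean run length in blocks.
#' @return The block series with missing runs flagged.
#' @export
inject_missing <- function(blocks, fraction, seed = 1L, mean_run = 2) {
  if (fraction < 0 || fraction >= 1) abort("fraction must lie in [0, 1)")
  if (fraction == 0) return(blocks)
  n <- nrow(blocks)
  set.seed(derive_seed(seed, 3))
  starts <- which(runif(n) < fraction / mean_run)
  lens <- 1L + stats::rgeom(length(starts), prob = 1 / mean_run)
  flagged <- unique(unlist(Map(function(s, l) s:min(n, s + l - 1L),
                               starts, lens)))
  blocks$missing[flagged] <- TRUE
  blocks$rate[flagged] <- NA_real_
  blocks$density[flagged] <- NA_real_
  blocks
}

#' Convert a simulated block series to a recombination map
#'
#' Bridges the simulator into the file-based path: the result can be written
#' with [write_recomb_map()] and re-read with [read_recomb_map()].
#'
#' @param blocks A simulated `block_series`.
#' @return A `recomb_map` tibble.
#' @export
blocks_to_recomb_map <- function(blocks) {
  bs <- attr(blocks, "block_size") %||% 10000L
  new_recomb_map(
    tibble::tibble(chrom = blocks$chrom, start = blocks$start,
                   end = blocks$start + bs,
                   rate = blocks$rate, missing = blocks$missing),
    bs
  )
}
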