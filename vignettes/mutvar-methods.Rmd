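---
title: "Models and methods behind mutvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mutvar` estimates how much of the fine-scale heterogeneity in single
nucleotide variant (SNV) density is attributable to meiotic recombination
and to local sequence context. This vignette records the models, the
assumptions behind them, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
a maintainer would want to know about.

## 1. The recombination regression

### Model

SNV density per genomic block (default 10 kb) is regressed on the block's
standardized recombination rate:

$$d_i = \alpha + \beta\, r_i + \varepsilon_i, \qquad
  \varepsilon \sim \mathrm{ARMA}(p, q),$$

with normal innovations. Plain OLS inference is invalid here because both
mutation and recombination rates are strongly autocorrelated between
neighbouring blocks; the residual ACF (`residual_acf()`) makes that
visible, and the `test-acceptance.R` coverage contrast demonstrates the
consequence: nominal-95% OLS intervals for the intercept cover the truth
far less often than advertised on autocorrelated simulations, while the
ARMA-error model is near-nominal.

The pipeline (`analyze_recombination()`) is: OLS baseline → residual ACF
→ augmented Dickey–Fuller stationarity check → AIC selection of (p, q)
over a grid with $1 \le p \le p_{max}$, $0 \le q \le q_{max}$ (defaults
10 and 4; non-converging fits are excluded from the ranking) → joint
Bayesian estimation of $(\alpha, \beta, \phi_{1..p}, \theta_{1..q},
\sigma)$ → derived statistics. Stationarity is a precondition for the
ARMA approximation (Wold's theorem); the verdict is `p < 0.05` by
default.

A p > 0 restriction is imposed on the grid: a pure-MA model cannot carry
the long-range decay the residuals show, and the selected order is only a
noise model, not an object of inference.

### Why a joint Bayesian fit

Two-stage procedures (fit a line, whiten the residuals, refit) propagate
no uncertainty between the stages, and iterative corrections of the
Cochrane–Orcutt type apply only to AR noise. Sampling $(\alpha, \beta)$
jointly with the ARMA coefficients conditions each on the full
uncertainty of the others; every derived statistic below is computed per
posterior draw so its credibility interval inherits all of it.

### Sampler

The posterior is explored by adaptive random-walk Metropolis:

* Likelihood: conditional sum of squares (CSS). With
  $z_i = d_i - \alpha - \beta r_i$, the AR part is removed by
  convolution, the innovations are recovered by the recursive filter
  $a_t = w_t - \sum_j \theta_j a_{t-j}$ (zero pre-sample innovations,
  conditioning on the first $p$ observations), and the log-likelihood is
  Gaussian in the $a_t$. CSS differs from the exact Kalman likelihood
  only through the treatment of the first few observations, negligible
  at the $n \ge 10^3$ series lengths this model is used at, and it
  vectorises fully.
* Priors: normals on $\alpha$ and $\beta$ centred at the OLS estimates
  with sd $10\times$ the OLS standard errors (weakly informative — wide
  enough that the likelihood dominates, centred so chains start in a
  sane region); flat priors on $(\phi, \theta)$ truncated to the
  stationary/invertible region (checked via polynomial roots); a
  half-normal on $\sigma$ with scale $5\times$ the OLS residual sd. The
  prior specification is attached to every fit object.
* Proposal: the ML fit of the same model (`stats::arima` with the rate
  as regressor) supplies the starting point and the initial proposal
  covariance, scaled by $2.38^2/d$; a diagonal fallback built from the
  OLS uncertainties is used when the ML fit fails. During the tuning
  phase the global scale is adapted towards a 0.234 acceptance rate and,
  at the end of tuning, the full proposal covariance is replaced by the
  empirical covariance of the second half of the tuning draws
  (Haario-style) and frozen.
* Layout: 4 chains × 2,000 retained draws after 1,000 tuning steps, with
  thinning 4 (each chain runs `tune + draws*thin` iterations). Thinning
  is what buys enough effective sample size for the strict convergence
  rule below at random-walk mixing rates.
* Convergence: split potential-scale-reduction (Rhat) per parameter,
  all required < 1.01. When the order came from `select_arma_order()`
  and diagnostics fail, the fit automatically retries with the
  next-AIC-ranked orders (up to rank 3) — the generalisation of falling
  back to the second-best order when the best one destabilises the MCMC
  — and errors with the full diagnostic report if all fail. Chains are
  initialised at the ML optimum plus a small proposal-scaled jitter.

### Derived statistics

Per posterior draw, with $m̄$ the mean observed SNV density:

* $\sigma^2_{rec} = \mathrm{Var}(d) - \overline{e^2}$ where $e$ are the
  *regression* residuals $d - (\alpha + \beta r)$ and both moments use
  the $1/n$ convention. "Mean squared residual" (not the raw sum of
  squares) is used so $\sigma^2_{rec}$ is commensurate with
  $\mathrm{Var}(d)$ and independent of series length; regression rather
  than whitened residuals because the quantity measures what
  recombination alone explains. $R^2 = \sigma^2_{rec}/\mathrm{Var}(d)$.
  $\sigma^2_{rec}$ is negative when the fit is worse than a flat line
  and is reported as-is.
* $\hat\rho = (m̄ - \alpha)/m̄$, the proportion of SNVs attributable to
  recombination, and
  $\text{mutations/crossover} = \hat\rho \cdot \mu / x$ with $\mu$ the
  point mutation rate and $x$ the crossover rate (defaults 1.19e-8 and
  1.16e-8 per bp per generation). Both are invariant to rescaling the
  block size.
* Slope conversions: one standardized rate unit corresponds to
  `mean_cM_per_block` centimorgans (default 0.0116 cM per 10-kb block),
  so `slope_per_cM = beta / mean_cM_per_block`, and multiplying by
  $\mu/m̄$ converts it to a mutation rate per bp per cM.
* `prob_slope_le_0`, the fraction of draws with $\beta \le 0$ — the
  per-direction evidence criterion (threshold 0.05 in the reports).

$m̄$ is computed from the observed (pre-imputation) densities of blocks
not repaired by LOCF; `m_bar = "series"` switches to the post-LOCF
series mean. The naive slope-based calculation
(`slope_implied_mutations_per_crossover_naive()`, slope/0.01) is kept as
comparison output; it attributes all recombination-associated mutations
to the current generation's crossovers and overestimates accordingly.

### Data qualification and LOCF

`build_block_series()` excludes blocks with no reported SNVs, blocks
flagged missing by the recombination map, and blocks adjacent to a
missing block ("adjacent" = one block each side, the minimal reading).
Excluded blocks inherit their nearest non-excluded 5′ neighbour's rate
and density (LOCF), which preserves the lag structure the ARMA model
needs; leading excluded blocks with no 5′ neighbour are dropped with a
message (the alternative — back-filling from 3′ — would invent a lag
direction). An excluded fraction above 5% of a chromosome warns but does
not stop the analysis. Per-direction densities divide by the count of
ancestral-base sites in the block, not block length — the only
denominator under which per-direction densities of different bases are
comparable.

## 2. Variance in SNV density due to context

### Model

Each site carries a fixed polymorphism probability that depends on its
k-mer context (k odd); sites are independent. Context proportions $p_c$
are treated as known because contexts are counted exactly
(`count_contexts()`); the per-context probabilities $m_c$ are unknown.
Each (k-mer, direction) cell is Binomial(trials = k-mer occurrences,
successes = qualified variants of that direction at the central base)
with a Beta(1, 1) prior, hence a Beta(1+s, 1+n−s) posterior. The
statistic

$$\sigma^2_k = \sum_{c} p_c (m_c - m̄)^2, \qquad m̄ = \sum_c p_c m_c$$

is sampled by drawing every cell's rate and evaluating the right-hand
side per draw. Conventional plug-in estimation would both hide the
uncertainty and inflate with the cell count ($4^k$ grows fast, and at
k = 7 most cells are small); the posterior draws carry the uncertainty
honestly. The known failure mode is the opposite: cells with *zero*
variants keep a uniform posterior and inflate the variance, so
`tally_cells()` warns when more than 1% of populated cells are empty
(tunable).

Variants qualify (`qualify_context_variants()`) only if biallelic with
the ancestral allele among the alleles, inside the mask, and with no
other variant within 4 bp on either side (disqualify iff distance ≤ 4;
every input variant disqualifies, including variants that themselves
fail other rules — the filters condition on the *presence* of variants).
On minus-strand intervals directions and contexts are
reverse-complemented so everything is read on the annotated strand of
the gene. Context windows must lie wholly inside their mask interval,
for both counting and tallying, so trials and successes always refer to
the same site set. A variant whose (oriented) ancestral base disagrees
with the genome base is counted as a mismatch and excluded; above 1%
mismatches the tally errors.

### The statistic's variants

* **Per direction** ($\sigma^2_k(a{\to}b)$): weights restricted and
  renormalised to contexts with central base $a$. The deviations are
  centred, by default, at the direction-specific mean
  $\sum p_c(a)\, m_{c,a\to b}$ — the only centring under which each
  component is a genuine variance, and the one the per-direction
  posterior analyses presuppose. `convention = "literal"` centres
  instead at $m̄_a$, the all-direction SNV rate of base $a$, preserving
  the printed form of the partition equation.
* **Marginalised**: k-mers sharing the same flanking (k−1)-mer are
  pooled (trials and successes summed over the 4 central bases and all
  directions), isolating the influence of the flanks alone. The pooled
  bins are sampled with the same beta scheme. On truth tables where
  rates depend only on the central base this is exactly zero; it can
  never exceed the total $\sigma^2_k$ (pooling cannot increase
  between-group variance).
* **CpG-conditioned**: the contribution
  $\sum_{c \in \mathrm{CpG}} p_c (m_c - m̄)^2$ of CpG-defined contexts
  (central C with 3′ G, plus the strand-symmetric central G with 5′ C)
  and its share of $\sigma^2_k$; subset and complement partition the
  total sum exactly. The transposed reading (central C with 5′ G /
  central G with 3′ C — GpC as standardly defined) is preserved behind
  `orientation = "gpc-literal"` because the two readings appear in the
  literature and the default should be the standard CpG dinucleotide.
* **Strand asymmetry**: a pair of strand-complementary directions is
  called asymmetric iff the 97.5 percentile of one posterior lies below
  the 2.5 percentile of the other.

### Determinism

All beta draws flow from one seed through a counter-based per-cell
stream (cell index = k-mer rank × direction rank), so adding or removing
cells does not perturb other cells' draws, every statistic that combines
cells regenerates identical per-cell draws, and identical seeds give
identical percentile reports. The marginalised statistic uses its own
seed namespace.

## 3. The synthetic-data generator

`simulate_blocks()` draws standardized rates from a gamma background
(shape 0.6) with a hotspot component (weight 0.02, multiplier 10),
re-standardized to mean 1 — a heavy-tailed, hotspot-dominated landscape
resembling pedigree-derived recombination maps; builds densities
`intercept + slope·rate + ARMA(p,q)` (defaults 0.026, 0.007, φ=0.5,
θ=0.3, innovation sd 0.003 — chosen so mean density, dynamic range and
residual autocorrelation sit in the regime of real per-10-kb SNV
densities); then resamples SNV counts Binomial(block_size, density),
because SNV counts are counts — this is exactly the heteroscedastic
noise OLS wrongly assumes away. Missingness arrives in runs (geometric,
mean 2) since the exclusion rules target runs of blocks.

`simulate_genome()` draws a sequence from configurable base frequencies
and, per site, an independent Bernoulli polymorphism indicator with
probability looked up from a `context_rate_table()` (base transversion
rate, transition multiplier, CpG multiplier, flank neighbour effects,
per-direction asymmetry multipliers); derived alleles are chosen among
the three directions in proportion to their rates. Multiallelic variants
and clustered variant pairs (within 4 bp) are injected afterwards to
exercise the filters. Rates apply to the plus-strand sequence; strand
enters only through analysis-side orientation, so asymmetric tables
produce genuinely strand-asymmetric data. Simulated data are written as
FASTA/VCF/BED/rmap and re-read through the package's own I/O, never
injected past it.

What the generator does *not* emulate: coalescent genealogy and linkage
(sites are independent), selection and biased gene conversion, mutation
clusters beyond simple proximity pairs, recurrent mutation, assembly
gaps, and any dependence of the recombination landscape on sequence.
Passing recovery tests therefore shows the estimators are correct for
the stated model, not that the model captures everything in real data.

## 4. Numerical choices and degenerate inputs

* Weighted-variance accumulation uses
  $\sigma^2 = \sum p_c m_c^2 - (\sum p_c m_c)^2$ (and the analogous
  cross-term expansion for subset contributions), streaming over cells —
  memory stays at O(draws) even at k = 7. Tiny negative values from
  floating-point cancellation are clamped to zero.
* The ADF test is the constant-only regression form with
  `trunc((n−1)^(1/3))` augmenting lags; p-values interpolate the
  Dickey–Fuller tau table (by sample size, then by statistic) and clamp
  with a message outside the tabulated 0.01–0.99 range.
* The mean-squared-residual per posterior draw is computed from the
  sufficient statistics of (x, y), exact and O(draws) instead of
  O(draws × n).
* Degenerate inputs error early and specifically: constant rate
  (singular design), zero-variance residual series, all-missing maps,
  empty context tables (weights cannot sum to 1), k even, variants out
  of genome bounds, unsorted or duplicated variant positions. An
  all-excluded chromosome is an error; a >5% excluded fraction is a
  warning by design.
* Sub-seeds for chains, cells and simulator stages derive from the one
  user seed by a fixed 32-bit multiplicative scheme, so everything stays
  below 2^31 and reruns are bit-identical.

## 5. Known limitations

* The ARMA likelihood is homoscedastic, but binomially resampled counts
  have variance growing with density, hence with rate. On simulations
  with the binomial layer on, slope credibility intervals are mildly
  anti-conservative (high-rate blocks carry both the slope information
  and the extra noise). The parameter-recovery calibration in the test
  suite is therefore run under the exact generative model (binomial
  stage off); a weighted or explicitly binomial observation layer would
  be the next modelling step.
* CSS conditioning discards the information in the first p observations;
  immaterial at thousands of blocks, but do not use this sampler on very
  short series.
* The beta-binomial cells assume independence across cells; overlapping
  k-mer windows of nearby sites violate this slightly. The ≥5 bp
  separation filter removes the worst of it, consistent with the model's
  own assumptions.
* `percentile()`-based strand-asymmetry verdicts are binary by
  construction; near-boundary cases flip under resampling, which is why
  the recovery studies run seed batteries rather than single genomes.
* Problem sizes in the test suite (5,000-block series; 0.5–10 Mb
  genomes; 20-seed batteries; 2 chains for battery fits, 4 for single
  fits) are the package's chosen compromise between Monte-Carlo
  resolution and a test suite that runs in minutes; all scale linearly
  if more resolution is wanted.

## 6. Design decisions that were genuinely open

* **Pooled multi-chromosome fits** are provided only through per-series
  fits on concatenated input; a common-slope model across chromosomes is
  deliberately not offered as a default because per-chromosome
  parameters differ enough to make a pooled intercept exceed the mean
  density — the same inconsistency that argues for per-chromosome
  reporting.
* **Disqualification distance**: "no variants within 4 bp on either
  side" is read as distance ≤ 4; the strict reading (minimum separation
  of 4, i.e. distance < 4 disqualifies) is available by passing
  `neighborhood = 3`.
* **Rate measurement error**: `rate_error_sd` adds a reproducible normal
  perturbation to the rates before fitting — a robustness check, off by
  default, not a latent-variable treatment.
* **m̄ before vs after LOCF**: default is before (observed blocks only),
  since imputed densities are copies, not observations; the flag exists
  because the choice is not forced by anything in the model.
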